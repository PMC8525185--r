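Package: ketascan
Title: Population Structure and Selection Scans for Salmon Stock-Identification Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genetic stock-identification (GSI) baseline
    data for chum salmon and similar high gene-flow species: bias-corrected
    Nei-Chesser G_ST pairwise F_ST estimation from allele frequencies,
    classical multidimensional scaling and neighbor-joining trees of the
    F_ST distance matrix, expected-heterozygosity and allele-frequency-spectrum
    summaries, island-model gene-flow connectivity graphs, and a per-locus
    regression scan that flags SNP loci whose allele frequencies deviate from
    the neutral (microsatellite-derived) population structure. Includes
    readers and writers for genepop, long-format allele-frequency tables,
    sampling-location tables and newick trees, and a seeded synthetic-data
    generator with a planted latitudinal cline, a diverged focal region,
    SNP ascertainment bias and planted outlier loci.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
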
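# ketascan

Population-structure inference and selection scans for genetic
stock-identification (GSI) baseline data, modelled on the chum salmon
(*Oncorhynchus keta*) marker panels used across the North Pacific rim.

GSI programs genotype hundreds of river populations at microsatellite and
SNP panels. Microsatellites behave approximately neutrally and carry the
demographic signal (gene flow and drift); GSI SNP panels, by contrast, were
often mined from rapidly evolving genes and discovered in a single region,
so their allele frequencies mix neutral structure with selection and
ascertainment bias. `ketascan` implements the analysis chain that separates
the two:

1. **Pairwise F_ST** between all populations with the bias-corrected
   Nei–Chesser G_ST moment estimator (NC83), per locus and combined over
   loci as a ratio of sums, directly from allele frequencies:
   with harmonic-mean sample size ñ,
   `ĤS = ñ/(ñ−1) · (hS − ĤO/2ñ)`, `ĤT = hT + ĤS/2ñ − ĤO/4ñ`,
   `G_ST = (ĤT − ĤS)/ĤT`.
2. **Structure inference**: classical MDS (principal coordinates) of the
   F_ST distance matrix with the cumulative contribution ratio
   `C_k = Σ_{j≤k} max(λ_j,0) / Σ_j max(λ_j,0)`, a neighbor-joining tree,
   and AIC bookkeeping for externally fitted TreeMix admixture graphs
   (three parameters per migration event).
3. **Diversity and connectivity**: expected heterozygosity
   `H_e = 1 − Σ p_k²`, regional allele-frequency spectra, and a gene-flow
   graph connecting pairs with `F_ST < 0.01` — about `4Nₑm = 1/F_ST − 1 ≈ 99`
   migrants per generation under Wright's island model.
4. **Selection scan**: match SNP sampling sites to the nearest
   microsatellite site (haversine distance), regress each SNP's allele
   frequency on the two leading neutral MDS axes,
   `p_ji = β0i + β1i·mds1_j + β2i·mds2_j + ε`, adjust p-values by
   Benjamini–Hochberg, and rank loci by `|β2|` (the axis separating the
   diverged focal region). A PCA of the SNP frequencies confirms the
   outliers.
5. **Synthetic data**: a seeded generator that plants the study conditions
   — a latitudinal cline, one strongly diverged "Japan/Korea-like" focal
   region, mean pairwise F_ST ≈ 0.019, microsatellite H_e ≈ 0.89,
   moderate SNP heterozygosity, discovery-region ascertainment filtering,
   and ~5 outlier loci — so the whole chain is testable without any
   external download.

## Worked example

```r
library(ketascan)

ls   <- simulate_structure(J = 60, seed = 7)          # coastline + regions
msat <- simulate_msat_frequencies(ls, seed = 8)       # neutral baseline
fst  <- pairwise_fst(msat)
#> Pairwise F_ST (NC83 G_ST, hwe, ratio_of_sums): 60 populations, 10 loci
#>   mean 0.0168, sd 0.0126, range [0.0011, 0.0714]

mds <- classical_mds(fst, k = 2)
#> Classical MDS: 60 populations, 2 retained axes
#>   cumulative contribution C_k: 0.653, 0.864

sim  <- simulate_snp_dataset(ls, L_neutral = 50, L_outlier = 5, seed = 9)
snp  <- genotypes_to_frequencies(sim$genotypes)
scan <- scan_loci(snp, mds, top_k = 5)
head(scan_table(scan), 6)
#>    locus abs_b1 neglog10_q1 abs_b2 neglog10_q2
#> 1 snp053   1.08       0.218   42.2        15.5
#> 2 snp055   2.71       1.113   40.1        20.6
#> 3 snp054   2.32       0.487   39.8        13.4
#> 4 snp051   4.88       2.208   37.8        17.0
#> 5 snp052   3.11       0.997   36.9        15.6
#> 6 snp005   3.37       6.686   15.0        19.9
```

The mean pairwise F_ST (0.017) sits at the weak-differentiation level
typical of high gene-flow salmon baselines; the two MDS axes carry 65% and
21% of the positive eigenvalue mass (the cline and the focal divergence).
The five loci planted with large focal-axis effects (`snp051`–`snp055`,
recorded in `sim$truth`) head the scan table with `|β2|` an order of
magnitude above the neutral background and q-values below `1e-13`, while
the best neutral locus (`snp005`) trails far behind — exactly the
deviation-from-neutral-structure signature the scan is built to detect.

The whole chain, plus diversity/connectivity summaries and PCA, also runs
as one reproducible pipeline:

```r
run_pipeline(default_config(seed = 7), out_dir = "run1")
# or from a shell:
#   Rscript inst/cli/ketascan.R --out run1 [--config cfg.yaml] [--seed 7]
```

which writes every table (F_ST matrices, MDS coordinates and eigenvalues,
newick tree, H_e and spectrum tables, connectivity edges, the Table-1-style
scan table, PCA scores/loadings), a JSON run report, and a MANIFEST of md5
checksums. Setting `config$inputs` to file paths (genepop genotypes,
long-format frequency CSVs, location TSVs) runs the same analysis on real
data instead of simulations.

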
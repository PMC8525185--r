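#' Default pipeline configuration
#'
#' The desk-scale defaults: 60 populations along the synthetic coastline,
#' 10 microsatellite-like loci (target mean pairwise G_ST 0.019, mean H_e
#' 0.89), 50 neutral + 5 outlier SNPs (effect scale 3 on the logit scale)
#' with focal-discovery ascertainment, one 5-allele mtDNA-like haploid
#' locus, and 50 individuals per population throughout.
#'
#' @param seed base RNG seed for the run
#' @return a nested configuration list understood by [run_pipeline()]
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    inputs = NULL,  # set file paths here to analyse real data instead
    simulation = list(
      J = 60, focal_fraction = 0.10, jitter_sd = 0.1,
      msat = list(L = 10, alleles_per_locus = 15, target_fst = 0.019,
                  mean_he_target = 0.89, n_per_pop = 50),
      snp = list(L_neutral = 50, L_outlier = 5, n_per_pop = 50,
                 effect_scale = 3, neutral_sd = 0.3,
                 ascertainment = "focal-discovery",
                 discovery_region = "Western Alaska", maf_min = 0.05),
      mtdna = list(n_alleles = 5, focal_major_freq = 0.21,
                   background_major_freq = 0.98, jitter_sd = 0.11,
                   n_per_pop = 50)
    ),
    estimator = list(ho_mode = "hwe", combine = "ratio_of_sums"),
    mds_axes = 2,
    connectivity_threshold = 0.01,
    spectrum = list(bins = 10, folded = TRUE),
    scan = list(covariates = "signed", bh_family = "per_coefficient",
                top_k = 5, q_cut = 0.05, focal_allele = NULL)
  )
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension); missing entries are filled from
#' [default_config()].
#'
#' @param path configuration file
#' @return a configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), cfg)
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> pairwise F_ST -> MDS + NJ tree ->
#' diversity, spectra and connectivity -> selection scan -> PCA, writing
#' every table to `out_dir` together with a JSON run report and a MANIFEST
#' of md5 checksums. The run is fully reproducible from the echoed
#' configuration: one base seed drives deterministically derived per-stage
#' sub-seeds.
#'
#' When `config$inputs` is set, the microsatellite frequency table, SNP
#' genepop file, optional mtDNA-like frequency table and the two location
#' tables are read from disk instead of simulated (fields `msat_freq`,
#' `msat_locations`, `snp_genepop`, `snp_locations`, `mtdna_freq`).
#'
#' @param config a configuration list ([default_config()]), or a path to a
#'   YAML/JSON configuration file
#' @param out_dir output directory (created if needed)
#' @param seed optional override of `config$seed`
#' @return invisibly, the run report list
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1

  # validate inputs before touching the output directory
  if (!is.null(config$inputs)) {
    need <- c("msat_freq", "msat_locations", "snp_genepop", "snp_locations")
    for (f in need) {
      if (is.null(config$inputs[[f]]))
        .stopf("config$inputs$%s is required for a file-based run", f)
      if (!file.exists(config$inputs[[f]]))
        .stopf("input file not found: %s", config$inputs[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)
  fail <- function(stage, e) {
    .write_manifest(out_dir, artifacts, complete = FALSE)
    .stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }

  set.seed(config$seed)
  sub_seed <- sample.int(2^31 - 2, 5)
  report <- list(package = "ketascan",
                 version = as.character(utils::packageVersion("ketascan")),
                 seed = config$seed)

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  add(file.path(out_dir, "config.yaml"))

  ## ---- stage: data ----
  truth <- NULL; mtdna <- NULL
  tryCatch({
    t0 <- Sys.time()
    if (is.null(config$inputs)) {
      sim <- config$simulation
      ls <- simulate_structure(sim$J, sim$focal_fraction,
                               jitter_sd = sim$jitter_sd, seed = sub_seed[1])
      msat <- do.call(simulate_msat_frequencies,
                      c(list(ls = ls, seed = sub_seed[2]), sim$msat))
      snp_sim <- do.call(simulate_snp_dataset,
                         c(list(ls = ls, seed = sub_seed[3]), sim$snp))
      truth <- snp_sim$truth
      snp <- genotypes_to_frequencies(snp_sim$genotypes)
      mtdna <- do.call(simulate_mtdna_locus,
                       c(list(ls = ls, seed = sub_seed[4]), sim$mtdna))
      write_locations(ls$locations, file.path(out_dir, "locations.tsv"))
      add(file.path(out_dir, "locations.tsv"))
      write_genepop(snp_sim$genotypes, file.path(out_dir, "snp_genotypes.gen"))
      add(file.path(out_dir, "snp_genotypes.gen"))
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           dataframe = "rows", digits = NA)
      add(file.path(out_dir, "truth.json"))
      snp_locs <- msat_locs <- ls$locations
    } else {
      msat_locs <- read_locations(config$inputs$msat_locations)
      snp_locs <- read_locations(config$inputs$snp_locations)
      msat <- read_frequency_table(config$inputs$msat_freq,
                                   locations = msat_locs)
      snp_gd <- read_genepop(config$inputs$snp_genepop)
      snp_gd$locations <- snp_locs[match(snp_gd$pops, snp_locs$id), ]
      snp <- genotypes_to_frequencies(snp_gd)
      if (!is.null(config$inputs$mtdna_freq))
        mtdna <- read_frequency_table(config$inputs$mtdna_freq, ploidy = 1,
                                      locations = snp_locs)
    }
    write_frequency_table(msat, file.path(out_dir, "msat_frequencies.csv"))
    add(file.path(out_dir, "msat_frequencies.csv"))
    write_frequency_table(snp, file.path(out_dir, "snp_frequencies.csv"))
    add(file.path(out_dir, "snp_frequencies.csv"))
    .log_stage("data", "%d msat pops x %d loci; %d SNP pops x %d loci (%.1fs)",
               length(msat$pops), length(msat$loci), length(snp$pops),
               length(snp$loci),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("data", e))

  ## ---- stage: fst ----
  tryCatch({
    t0 <- Sys.time()
    fst_msat <- pairwise_fst(msat, ho_mode = config$estimator$ho_mode,
                             combine = config$estimator$combine)
    fst_snp <- pairwise_fst(snp, ho_mode = config$estimator$ho_mode,
                            combine = config$estimator$combine)
    write_fst_matrix(fst_msat, file.path(out_dir, "fst_msat.csv"))
    add(file.path(out_dir, "fst_msat.csv"))
    add(file.path(out_dir, "fst_msat.csv.flags.json"))
    write_fst_matrix(fst_snp, file.path(out_dir, "fst_snp.csv"))
    add(file.path(out_dir, "fst_snp.csv"))
    add(file.path(out_dir, "fst_snp.csv.flags.json"))
    off <- fst_msat$fst[upper.tri(fst_msat$fst)]
    report$fst <- list(msat_mean = mean(off, na.rm = TRUE),
                       msat_sd = stats::sd(off, na.rm = TRUE))
    .log_stage("fst", "msat mean pairwise F_ST %.4f (%.1fs)",
               report$fst$msat_mean,
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("fst", e))

  ## ---- stage: structure ----
  tryCatch({
    t0 <- Sys.time()
    mds <- suppressWarnings(classical_mds(fst_msat, k = config$mds_axes))
    coords <- data.frame(population = rownames(mds$points), mds$points,
                         region = msat$locations$region
                           %||% rep(NA, nrow(mds$points)))
    .write_csv(coords, file.path(out_dir, "mds_coords.csv"))
    add(file.path(out_dir, "mds_coords.csv"))
    .write_csv(data.frame(axis = seq_along(mds$eig), eigenvalue = mds$eig,
                          C_k = mds$C),
               file.path(out_dir, "mds_eigen.csv"))
    add(file.path(out_dir, "mds_eigen.csv"))
    tree <- suppressWarnings(nj_tree(fst_msat))
    write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
    add(file.path(out_dir, "nj_tree.nwk"))
    report$mds <- list(C1 = mds$C[1], C2 = mds$C[2],
                       axis_share_1 = explained_variation(mds$eig, 1),
                       axis_share_2 = mds$C[2] - mds$C[1])
    .log_stage("structure", "C_1 %.3f, C_2 %.3f; NJ tree %d tips (%.1fs)",
               mds$C[1], mds$C[2], length(tree$tip.label),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("structure", e))

  ## ---- stage: diversity ----
  tryCatch({
    t0 <- Sys.time()
    div_m <- expected_heterozygosity(msat)
    div_s <- expected_heterozygosity(snp)
    for (nm in c("msat", "snp")) {
      d <- if (nm == "msat") div_m else div_s
      col <- color_gradient(d$pop_mean)
      .write_csv(data.frame(population = names(d$pop_mean),
                            mean_he = d$pop_mean, loci_used = d$loci_used,
                            region = d$region %||% NA, col),
                 file.path(out_dir, sprintf("diversity_%s.csv", nm)))
      add(file.path(out_dir, sprintf("diversity_%s.csv", nm)))
    }
    spec <- allele_frequency_spectrum(snp, bins = config$spectrum$bins,
                                      folded = config$spectrum$folded)
    .write_csv(data.frame(region = rownames(spec$counts), spec$counts,
                          check.names = FALSE),
               file.path(out_dir, "spectrum_snp.csv"))
    add(file.path(out_dir, "spectrum_snp.csv"))
    conn_m <- connectivity_edges(fst_msat, config$connectivity_threshold)
    conn_s <- connectivity_edges(fst_snp, config$connectivity_threshold)
    .write_csv(conn_m$edges, file.path(out_dir, "connectivity_msat.csv"))
    add(file.path(out_dir, "connectivity_msat.csv"))
    .write_csv(conn_s$edges, file.path(out_dir, "connectivity_snp.csv"))
    add(file.path(out_dir, "connectivity_snp.csv"))
    report$diversity <- list(msat_mean_he = div_m$overall_mean,
                             msat_sd_he = div_m$overall_sd,
                             snp_mean_he = div_s$overall_mean,
                             snp_sd_he = div_s$overall_sd)
    report$connectivity <- list(msat_edges = nrow(conn_m$edges),
                                snp_edges = nrow(conn_s$edges),
                                threshold = config$connectivity_threshold)
    .log_stage("diversity",
               "msat He %.3f, snp He %.3f; %d/%d connectivity edges (%.1fs)",
               div_m$overall_mean, div_s$overall_mean, nrow(conn_m$edges),
               nrow(conn_s$edges),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("diversity", e))

  ## ---- stage: scan ----
  tryCatch({
    t0 <- Sys.time()
    match <- match_locations(snp_locs, msat_locs)
    .write_csv(match, file.path(out_dir, "location_match.csv"))
    add(file.path(out_dir, "location_match.csv"))
    scan_ds <- snp
    focal <- config$scan$focal_allele
    if (!is.null(mtdna)) {
      scan_ds <- merge_afreq_loci(snp, mtdna)
      if (is.null(focal) && is.null(config$inputs)) {
        # simulated mtDNA-like locus: scan its major allele (listed second)
        focal <- stats::setNames(mtdna$alleles[[1]][2], mtdna$loci[1])
      }
    }
    scan <- scan_loci(scan_ds, mds, match = match,
                      top_k = config$scan$top_k, q_cut = config$scan$q_cut,
                      focal_allele = focal,
                      covariates = config$scan$covariates,
                      bh_family = config$scan$bh_family)
    .write_csv(scan_table(scan), file.path(out_dir, "scan_table.csv"))
    add(file.path(out_dir, "scan_table.csv"))
    jsonlite::write_json(scan$records, file.path(out_dir, "scan_records.json"),
                         dataframe = "rows", digits = NA)
    add(file.path(out_dir, "scan_records.json"))
    report$scan <- list(n_loci = nrow(scan$records),
                        outliers = as.list(scan$outliers))
    if (!is.null(truth)) {
      planted <- truth$locus[truth$is_outlier]
      report$scan$planted_outliers <- as.list(planted)
      report$scan$sensitivity <-
        if (length(planted)) mean(planted %in% scan$outliers) else NA
    }
    .log_stage("scan", "%d loci scanned; outliers: %s (%.1fs)",
               nrow(scan$records), paste(scan$outliers, collapse = ", "),
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("scan", e))

  ## ---- stage: pca ----
  tryCatch({
    t0 <- Sys.time()
    fm <- focal_allele_matrix(scan_ds, focal)
    fm <- fm[, colSums(is.na(fm)) == 0, drop = FALSE]
    pca <- pca_allele_frequencies(fm)
    .write_csv(data.frame(population = rownames(pca$scores),
                          pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                     drop = FALSE]),
               file.path(out_dir, "pca_scores.csv"))
    add(file.path(out_dir, "pca_scores.csv"))
    .write_csv(data.frame(locus = rownames(pca$loadings),
                          pca$loadings[, seq_len(min(4, ncol(pca$loadings))),
                                       drop = FALSE]),
               file.path(out_dir, "pca_loadings.csv"))
    add(file.path(out_dir, "pca_loadings.csv"))
    .write_csv(data.frame(component = seq_along(pca$var_prop),
                          var_prop = pca$var_prop),
               file.path(out_dir, "pca_variance.csv"))
    add(file.path(out_dir, "pca_variance.csv"))
    report$pca <- list(pc1_var = pca$var_prop[1], pc2_var = pca$var_prop[2])
    .log_stage("pca", "PC1 %.1f%%, PC2 %.1f%% (%.1fs)",
               100 * pca$var_prop[1], 100 * pca$var_prop[2],
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) fail("pca", e))

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add(file.path(out_dir, "report.json"))
  .write_manifest(out_dir, artifacts, complete = TRUE)
  invisible(report)
}

.write_manifest <- function(out_dir, artifacts, complete) {
  artifacts <- artifacts[file.exists(artifacts)]
  df <- data.frame(file = basename(artifacts),
                   md5 = unname(tools::md5sum(artifacts)),
                   bytes = unname(file.size(artifacts)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$file), , drop = FALSE]
  lines <- c(sprintf("# ketascan run manifest (%s)",
                     if (complete) "complete" else "INCOMPLETE"),
             sprintf("%s  %s  %d", df$md5, df$file, df$bytes))
  writeLines(lines, file.path(out_dir, "MANIFEST"))
}
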
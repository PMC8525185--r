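#' Match SNP sampling locations to microsatellite sampling locations
#'
#' Case-insensitive exact name matches are taken first; remaining sites are
#' assigned the nearest microsatellite site by haversine great-circle
#' distance (Earth radius 6371 km), with ties broken by the
#' lexicographically smallest microsatellite id. Every SNP site gets
#' exactly one match; the distance is reported for exact matches too.
#'
#' @param snp_locs,msat_locs sampling-location `data.frame`s
#'   (see [read_locations()])
#' @return a `data.frame`: `snp_id`, `msat_id`, `match_type`
#'   (`"exact-name"` or `"nearest"`), `distance_km`
#' @export
match_locations <- function(snp_locs, msat_locs) {
  if (!nrow(snp_locs) || !nrow(msat_locs))
    .stopf("both location lists must be non-empty")
  msat_name <- tolower(trimws(msat_locs$name))
  out <- data.frame(snp_id = snp_locs$id, msat_id = NA_character_,
                    match_type = NA_character_, distance_km = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(snp_locs))) {
    hit <- which(msat_name == tolower(trimws(snp_locs$name[i])))
    d <- haversine_km(snp_locs$latitude[i], snp_locs$longitude[i],
                      msat_locs$latitude, msat_locs$longitude)
    if (length(hit)) {
      hit <- hit[order(msat_locs$id[hit])][1]
      out$msat_id[i] <- msat_locs$id[hit]
      out$match_type[i] <- "exact-name"
      out$distance_km[i] <- d[hit]
    } else {
      near <- which(d <= min(d) + 1e-9)
      near <- near[order(msat_locs$id[near])][1]
      out$msat_id[i] <- msat_locs$id[near]
      out$match_type[i] <- "nearest"
      out$distance_km[i] <- d[near]
    }
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and
#' mapped back to the input order.
#'
#' @param pvals p-values in `[0, 1]`
#' @return q-values in input order
#' @export
benjamini_hochberg <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Regress one locus's allele frequencies on two MDS axes
#'
#' Ordinary least squares for `p_j = b0 + b1 * mds1_j + b2 * mds2_j + e_j`,
#' `e ~ N(0, s2)`, giving coefficient estimates, standard errors from
#' `s2_hat * (X'X)^-1` with `s2_hat = RSS / (J - 3)`, and two-sided
#' p-values from the t distribution on `J - 3` degrees of freedom.
#' Populations with a missing frequency are dropped pairwise (count
#' recorded in the result).
#'
#' @param p per-population focal-allele frequencies of one locus
#' @param mds1,mds2 MDS axis values for the same populations
#' @param locus optional locus name carried into the record
#' @return a one-row `data.frame`: `locus`, `b0`, `b1`, `b2`, `se0`, `se1`,
#'   `se2`, `t0`, `t1`, `t2`, `p0`, `p1`, `p2`, `sigma2`, `n_used`,
#'   `n_dropped`
#' @export
regress_locus <- function(p, mds1, mds2, locus = NA_character_) {
  if (length(p) != length(mds1) || length(p) != length(mds2))
    .stopf("p, mds1 and mds2 must have equal length")
  keep <- !is.na(p) & !is.na(mds1) & !is.na(mds2)
  n_dropped <- sum(!keep)
  p <- p[keep]; mds1 <- mds1[keep]; mds2 <- mds2[keep]
  J <- length(p)
  if (J < 4) .stopf("at least 4 populations required (residual df >= 1)")
  if (stats::var(p) == 0) {
    # constant response: slopes are exactly 0, nothing to test
    return(data.frame(locus = locus, b0 = p[1], b1 = 0, b2 = 0,
                      se0 = 0, se1 = 0, se2 = 0, t0 = NA_real_, t1 = 0, t2 = 0,
                      p0 = NA_real_, p1 = 1, p2 = 1, sigma2 = 0,
                      n_used = J, n_dropped = n_dropped,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(p ~ mds1 + mds2)
  if (any(is.na(stats::coef(fit))))
    .stopf("rank-deficient design: mds1 and mds2 are collinear")
  sm <- summary(fit)$coefficients
  data.frame(locus = locus,
             b0 = sm[1, 1], b1 = sm[2, 1], b2 = sm[3, 1],
             se0 = sm[1, 2], se1 = sm[2, 2], se2 = sm[3, 2],
             t0 = sm[1, 3], t1 = sm[2, 3], t2 = sm[3, 3],
             p0 = sm[1, 4], p1 = sm[2, 4], p2 = sm[3, 4],
             sigma2 = sum(stats::resid(fit)^2) / (J - 3),
             n_used = J, n_dropped = n_dropped,
             stringsAsFactors = FALSE)
}

#' Focal-allele frequency matrix
#'
#' Summarizes each locus by one allele's frequency per population. The
#' default focal allele is the second-most-frequent allele overall (for a
#' biallelic SNP this is the overall minor allele; for the multi-allelic
#' mtDNA-like locus it matches using the major allele when the catalogue
#' lists it second). Per-locus overrides are accepted.
#'
#' @param ds an [afreq_dataset()]
#' @param focal_allele optional named character vector locus -> allele name
#' @return a populations x loci numeric matrix
#' @export
focal_allele_matrix <- function(ds, focal_allele = NULL) {
  stopifnot(inherits(ds, "afreq_dataset"))
  out <- matrix(NA_real_, length(ds$pops), length(ds$loci),
                dimnames = list(ds$pops, ds$loci))
  for (l in ds$loci) {
    m <- ds$freq[[l]]
    al <- colnames(m)
    if (!is.null(focal_allele) && l %in% names(focal_allele)) {
      a <- focal_allele[[l]]
      if (!a %in% al) .stopf("locus '%s': focal allele '%s' not in catalogue", l, a)
    } else {
      mean_f <- colMeans(m, na.rm = TRUE)
      a <- if (length(al) > 1) al[order(-mean_f)][2] else al[1]
    }
    out[, l] <- m[, a]
  }
  out
}

#' Selection scan: regress SNP allele frequencies on the neutral structure
#'
#' The headline procedure: every SNP locus's focal-allele frequency is
#' regressed on the first two MDS axes of the neutral (microsatellite)
#' pairwise F_ST structure, evaluated at each SNP population's matched
#' microsatellite population. Per-coefficient p-values are BH-adjusted
#' across loci, separately per coefficient family by default. Records are
#' ranked by descending `|b2|` (the focal-region axis); the outlier set is
#' the top `top_k` ranked loci with `q(b2) < q_cut`.
#'
#' @param snp_freqs an [afreq_dataset()] of SNP (and mtDNA-like) loci
#' @param mds an `mds_result` from [classical_mds()] on the neutral F_ST
#'   matrix (axes 1 and 2 are used)
#' @param match optional match table from [match_locations()]
#'   (`snp_id` -> `msat_id`); omit when the SNP populations are themselves
#'   labelled with MDS population names
#' @param top_k number of top-ranked loci reported as outliers
#' @param q_cut q-value cut applied to the `b2` family for outlier calls
#' @param focal_allele per-locus focal-allele overrides
#'   (see [focal_allele_matrix()])
#' @param covariates `"signed"` (default; the regression model's raw axes)
#'   or `"absolute"` (regress on `|mds1|`, `|mds2|`)
#' @param bh_family `"per_coefficient"` (default: one BH family per axis
#'   across loci) or `"pooled"`
#' @param max_missing exclude a locus absent in more than this fraction of
#'   matched populations (default 0.5), with a warning
#' @return an object of class `selection_scan`: `records` (one row per
#'   locus, sorted by descending `|b2|`, with `q1`, `q2`,
#'   `neglog10_q1`, `neglog10_q2`, `abs_b1`, `abs_b2`), `outliers`
#'   (character vector), plus the options used
#' @export
scan_loci <- function(snp_freqs, mds, match = NULL, top_k = 5, q_cut = 0.05,
                      focal_allele = NULL,
                      covariates = c("signed", "absolute"),
                      bh_family = c("per_coefficient", "pooled"),
                      max_missing = 0.5) {
  stopifnot(inherits(snp_freqs, "afreq_dataset"), inherits(mds, "mds_result"))
  covariates <- match.arg(covariates)
  bh_family <- match.arg(bh_family)
  if (ncol(mds$points) < 2) .stopf("MDS result must retain at least 2 axes")
  pops <- snp_freqs$pops
  if (!is.null(match)) {
    if (!all(pops %in% match$snp_id))
      .stopf("match table must cover every SNP population")
    target <- match$msat_id[base::match(pops, match$snp_id)]
  } else target <- pops
  if (!all(target %in% rownames(mds$points)))
    .stopf("matched populations missing from the MDS result")
  X <- mds$points[target, 1:2, drop = FALSE]
  if (covariates == "absolute") X <- abs(X)

  fm <- focal_allele_matrix(snp_freqs, focal_allele)
  records <- list(); skipped <- character(0)
  for (l in snp_freqs$loci) {
    p <- fm[, l]
    if (mean(is.na(p)) > max_missing) { skipped <- c(skipped, l); next }
    rec <- tryCatch(regress_locus(p, X[, 1], X[, 2], locus = l),
                    error = function(e) NULL)
    if (is.null(rec)) { skipped <- c(skipped, l); next }
    records[[l]] <- rec
  }
  if (length(skipped))
    warning(sprintf("excluded %d locus/loci (missing data or degenerate fit): %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  if (!length(records)) .stopf("no locus could be scanned")
  rec <- do.call(rbind, records)
  if (bh_family == "per_coefficient") {
    rec$q1 <- benjamini_hochberg(rec$p1)
    rec$q2 <- benjamini_hochberg(rec$p2)
  } else {
    q <- benjamini_hochberg(c(rec$p1, rec$p2))
    rec$q1 <- q[seq_len(nrow(rec))]
    rec$q2 <- q[nrow(rec) + seq_len(nrow(rec))]
  }
  rec$abs_b1 <- abs(rec$b1)
  rec$abs_b2 <- abs(rec$b2)
  rec$neglog10_q1 <- -log10(rec$q1)
  rec$neglog10_q2 <- -log10(rec$q2)
  rec <- rec[order(-rec$abs_b2), , drop = FALSE]
  rownames(rec) <- NULL
  ranked <- rec$locus[seq_len(min(top_k, nrow(rec)))]
  outliers <- ranked[rec$q2[seq_len(length(ranked))] < q_cut]
  structure(list(records = rec, outliers = outliers, skipped = skipped,
                 top_k = top_k, q_cut = q_cut, covariates = covariates,
                 bh_family = bh_family),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf("Selection scan: %d loci (%d excluded), covariates=%s, BH=%s\n",
              nrow(x$records), length(x$skipped), x$covariates, x$bh_family))
  cat(sprintf("  outliers (top %d by |b2|, q2 < %g): %s\n", x$top_k, x$q_cut,
              if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none"))
  invisible(x)
}

#' Scan results as a compact report table
#'
#' One row per locus, ordered by descending `|b2|`: locus, `|b1|`,
#' `-log10 q(b1)`, `|b2|`, `-log10 q(b2)`.
#'
#' @param scan a `selection_scan`
#' @return a `data.frame`
#' @export
scan_table <- function(scan) {
  stopifnot(inherits(scan, "selection_scan"))
  r <- scan$records
  data.frame(locus = r$locus, abs_b1 = r$abs_b1,
             neglog10_q1 = r$neglog10_q1, abs_b2 = r$abs_b2,
             neglog10_q2 = r$neglog10_q2, stringsAsFactors = FALSE)
}

#' PCA of population allele frequencies
#'
#' Column-centred (not variance-scaled: frequencies share a scale)
#' principal components of a populations x loci focal-allele frequency
#' matrix. Zero-variance columns are dropped with a warning. Axis
#' orientation follows the [classical_mds()] convention: the population
#' with the largest-magnitude score is positive on each component.
#'
#' @param freq_matrix populations x loci numeric matrix, e.g. from
#'   [focal_allele_matrix()]
#' @return an object of class `pca_result`: `scores`, `loadings`,
#'   `var_prop`, `sdev`
#' @export
pca_allele_frequencies <- function(freq_matrix) {
  x <- as.matrix(freq_matrix)
  if (nrow(x) < 3 || ncol(x) < 2) .stopf("need >= 3 populations and >= 2 loci")
  if (anyNA(x)) .stopf("missing frequencies; impute or drop populations first")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropped %d zero-variance locus/loci", sum(v == 0)),
            call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) .stopf("fewer than 2 non-constant loci")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  for (a in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, a]))
    if (scores[i, a] < 0) {
      scores[, a] <- -scores[, a]
      loadings[, a] <- -loadings[, a]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 var_prop = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d populations, %d loci\n", nrow(x$scores), nrow(x$loadings)))
  k <- min(4, length(x$var_prop))
  cat(sprintf("  variance shares: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_prop[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}
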
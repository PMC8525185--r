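#' Bias-corrected Nei-Chesser G_ST components for one locus, two populations
#'
#' Implements the Nei & Chesser (1983) sample-size-corrected moment
#' estimators of within-population (`HS`) and total (`HT`) gene diversity
#' for the two-population case. With harmonic-mean sample size
#' `nh = 2 / (1/n1 + 1/n2)` (diploid individuals),
#' `hS = 1 - (sum(p1^2) + sum(p2^2)) / 2`, `hT = 1 - sum(((p1+p2)/2)^2)`:
#'
#' \deqn{\hat H_S = \frac{\tilde n}{\tilde n - 1}\left(h_S - \frac{\hat H_O}{2\tilde n}\right),\qquad
#'       \hat H_T = h_T + \frac{\hat H_S}{2\tilde n} - \frac{\hat H_O}{4\tilde n}.}
#'
#' Frequency-only data carry no observed heterozygosity, so by default
#' `H_O` is replaced by its Hardy-Weinberg expectation `hS` (`ho = NULL`);
#' pass the observed value when genotypes are available.
#'
#' The locus G_ST is `(HT - HS) / HT`; a locus fixed for the same allele in
#' both populations gives `HT = HS = 0` and is uninformative.
#'
#' @param p1,p2 allele-frequency vectors over a shared allele catalogue,
#'   each summing to 1
#' @param n1,n2 sample sizes in diploid individuals (both `>= 2`)
#' @param ho observed heterozygosity (average of the two populations), or
#'   `NULL` for the HWE substitution
#' @return a list with `HT`, `HS`, and `gst` (`NA` when `HT == 0`)
#' @references Nei M, Chesser RK (1983) Estimation of fixation indices and
#'   gene diversities. Annals of Human Genetics 47, 253-259.
#' @export
gst_nc83_locus <- function(p1, p2, n1, n2, ho = NULL) {
  if (length(p1) != length(p2))
    .stopf("mismatched allele catalogues (%d vs %d alleles)", length(p1), length(p2))
  if (!is.null(names(p1)) && !is.null(names(p2)) && !identical(names(p1), names(p2)))
    .stopf("mismatched allele catalogues (different allele names)")
  if (abs(sum(p1) - 1) > 1e-6 || abs(sum(p2) - 1) > 1e-6)
    .stopf("frequency vectors must sum to 1")
  if (n1 < 2 || n2 < 2) .stopf("sample sizes must be >= 2 for the bias correction")
  nh <- 2 / (1 / n1 + 1 / n2)
  hs <- 1 - (sum(p1^2) + sum(p2^2)) / 2
  ht <- 1 - sum(((p1 + p2) / 2)^2)
  if (is.null(ho)) ho <- hs
  HS <- nh / (nh - 1) * (hs - ho / (2 * nh))
  HT <- ht + HS / (2 * nh) - ho / (4 * nh)
  list(HT = HT, HS = HS, gst = if (HT != 0) (HT - HS) / HT else NA_real_)
}

#' Pairwise multilocus F_ST matrix (bias-corrected G_ST)
#'
#' Computes the Nei-Chesser (1983) bias-corrected G_ST for every population
#' pair, combining loci as a ratio of sums,
#' `G_ST = sum_l (HT_l - HS_l) / sum_l HT_l`, over the loci usable in both
#' populations of the pair (pairwise-complete). Ratio-of-sums is the
#' standard multilocus practice; the unstable mean of per-locus ratios is
#' available for sensitivity checks via `combine`.
#'
#' Pairs with `sum(HT) == 0` at every usable locus (or no shared usable
#' locus) are flagged undefined rather than silently set to 0. Negative
#' estimates (possible after bias correction at weak differentiation) are
#' reported as-is.
#'
#' For haploid loci the sample-size unit is the haplotype: with
#' harmonic-mean gene copies `g`, `HS = g/(g-1) * hS` and `HT = hT + HS/g`.
#'
#' @param ds an [afreq_dataset()]
#' @param loci optional character vector restricting the loci used
#' @param per_locus keep the per-locus matrices in the result?
#' @param ho_mode `"hwe"` (frequency-only data: substitute the HWE
#'   expectation for observed heterozygosity) or `"observed"` (requires a
#'   dataset built by [genotypes_to_frequencies()])
#' @param combine `"ratio_of_sums"` (default) or `"mean_of_ratios"`
#' @return an object of class `fst_matrix`: list with `fst` (J x J,
#'   symmetric, zero diagonal), `defined` (logical J x J), `pops`,
#'   `loci`, and optionally `per_locus`
#' @export
pairwise_fst <- function(ds, loci = NULL, per_locus = FALSE,
                         ho_mode = c("hwe", "observed"),
                         combine = c("ratio_of_sums", "mean_of_ratios")) {
  stopifnot(inherits(ds, "afreq_dataset"))
  ho_mode <- match.arg(ho_mode)
  combine <- match.arg(combine)
  if (ho_mode == "observed" && is.null(ds$het))
    .stopf("ho_mode='observed' needs observed heterozygosities (genotype-derived data)")
  loci <- loci %||% ds$loci
  if (!all(loci %in% ds$loci)) .stopf("unknown loci requested")
  J <- length(ds$pops)
  if (J < 2) .stopf("at least two populations required")
  sumT <- matrix(0, J, J); sumD <- matrix(0, J, J)
  sumR <- matrix(0, J, J); nloc <- matrix(0L, J, J); ninf <- matrix(0L, J, J)
  pl <- if (per_locus) stats::setNames(vector("list", length(loci)), loci) else NULL

  for (l in loci) {
    P <- ds$freq[[l]]
    nvec <- ds$n[, l]
    present <- !is.na(nvec) & !apply(is.na(P), 1, any)
    if (sum(present) < 2) next
    g <- ds$ploidy[l] * nvec            # gene copies sampled
    s2 <- rowSums(P^2)
    avail <- outer(present, present, "&")
    ssum <- outer(s2, s2, "+")
    cross <- P; cross[is.na(cross)] <- 0
    cross <- cross %*% t(cross)
    hs <- 1 - ssum / 2
    ht <- 1 - (ssum + 2 * cross) / 4
    gh <- 2 / (outer(1 / g, 1 / g, "+"))  # harmonic-mean gene copies
    if (ds$ploidy[l] == 2L) {
      nh <- gh / 2
      if (ho_mode == "observed") {
        hv <- ds$het[, l]
        Ho <- outer(hv, hv, "+") / 2
      } else Ho <- hs
      HS <- nh / (nh - 1) * (hs - Ho / (2 * nh))
      HT <- ht + HS / (2 * nh) - Ho / (4 * nh)
    } else {
      HS <- gh / (gh - 1) * hs
      HT <- ht + HS / gh
    }
    HS[!avail] <- NA; HT[!avail] <- NA
    ok <- avail
    sumT[ok] <- sumT[ok] + HT[ok]
    sumD[ok] <- sumD[ok] + (HT[ok] - HS[ok])
    informative <- ok & HT != 0
    sumR[informative] <- sumR[informative] +
      (HT[informative] - HS[informative]) / HT[informative]
    ninf[informative] <- ninf[informative] + 1L
    nloc[ok] <- nloc[ok] + 1L
    if (per_locus) {
      m <- (HT - HS) / HT
      m[!avail] <- NA
      diag(m) <- 0
      dimnames(m) <- list(ds$pops, ds$pops)
      pl[[l]] <- m
    }
  }
  defined <- nloc > 0L & sumT != 0
  diag(defined) <- TRUE
  if (!any(defined[upper.tri(defined)]))
    .stopf("all population pairs undefined (no shared usable loci)")
  fst <- if (combine == "ratio_of_sums") sumD / sumT else sumR / pmax(ninf, 1L)
  fst[!defined] <- NA
  diag(fst) <- 0
  dimnames(fst) <- dimnames(defined) <- list(ds$pops, ds$pops)
  structure(list(fst = fst, defined = defined, pops = ds$pops, loci = loci,
                 per_locus = pl, ho_mode = ho_mode, combine = combine),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  off <- x$fst[upper.tri(x$fst)]
  cat(sprintf("Pairwise F_ST (NC83 G_ST, %s, %s): %d populations, %d loci\n",
              x$ho_mode, x$combine, length(x$pops), length(x$loci)))
  cat(sprintf("  mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
              mean(off, na.rm = TRUE), stats::sd(off, na.rm = TRUE),
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  und <- sum(!x$defined[upper.tri(x$defined)])
  if (und) cat(sprintf("  undefined pairs: %d\n", und))
  invisible(x)
}

#' Write an F_ST matrix as square CSV plus a JSON sidecar of undefined pairs
#' @param fst an `fst_matrix`
#' @param path CSV output path; the sidecar is written to `<path>.flags.json`
#' @return `path`, invisibly
#' @export
write_fst_matrix <- function(fst, path) {
  stopifnot(inherits(fst, "fst_matrix"))
  utils::write.csv(as.data.frame(fst$fst), path, row.names = TRUE)
  und <- which(!fst$defined & upper.tri(fst$defined), arr.ind = TRUE)
  flags <- if (nrow(und)) {
    data.frame(pop_a = fst$pops[und[, 1]], pop_b = fst$pops[und[, 2]],
               status = "undefined")
  } else data.frame(pop_a = character(0), pop_b = character(0),
                    status = character(0))
  jsonlite::write_json(flags, paste0(path, ".flags.json"), dataframe = "rows")
  invisible(path)
}
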
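#' Expected heterozygosity summary
#'
#' `H_e = 1 - sum(p_k^2)` per population x locus, averaged over the usable
#' loci for each population, with per-region means and standard deviations
#' when the dataset carries sampling locations (or a `region` vector is
#' supplied).
#'
#' @param ds an [afreq_dataset()]
#' @param region optional named character vector mapping population id to
#'   region; defaults to the dataset's location table
#' @return an object of class `diversity_summary`: `he` (J x L matrix),
#'   `pop_mean`, `loci_used` (per-population count), `region`,
#'   `region_stats` (`data.frame`: region, mean, sd, n_pops),
#'   `overall_mean`, `overall_sd`
#' @export
expected_heterozygosity <- function(ds, region = NULL) {
  stopifnot(inherits(ds, "afreq_dataset"))
  he <- sapply(ds$loci, function(l) 1 - rowSums(ds$freq[[l]]^2))
  if (is.null(dim(he))) he <- matrix(he, nrow = length(ds$pops),
                                     dimnames = list(ds$pops, ds$loci))
  pop_mean <- rowMeans(he, na.rm = TRUE)
  loci_used <- rowSums(!is.na(he))
  if (is.null(region) && !is.null(ds$locations))
    region <- stats::setNames(ds$locations$region, ds$locations$id)
  region_stats <- NULL
  if (!is.null(region)) {
    reg <- region[ds$pops]
    region_stats <- do.call(rbind, lapply(split(pop_mean, reg), function(v) {
      data.frame(mean = mean(v), sd = stats::sd(v), n_pops = length(v))
    }))
    region_stats <- data.frame(region = rownames(region_stats), region_stats,
                               row.names = NULL)
  }
  structure(list(he = he, pop_mean = pop_mean, loci_used = loci_used,
                 region = if (!is.null(region)) region[ds$pops] else NULL,
                 region_stats = region_stats,
                 overall_mean = mean(pop_mean), overall_sd = stats::sd(pop_mean)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("Expected heterozygosity: %d populations, %d loci\n",
              nrow(x$he), ncol(x$he)))
  cat(sprintf("  overall mean H_e = %.3f +/- %.3f (range %.3f-%.3f)\n",
              x$overall_mean, x$overall_sd, min(x$pop_mean), max(x$pop_mean)))
  if (!is.null(x$region_stats)) {
    cat("  by region:\n")
    for (i in seq_len(nrow(x$region_stats)))
      cat(sprintf("    %-18s %.3f (n=%d)\n", x$region_stats$region[i],
                  x$region_stats$mean[i], x$region_stats$n_pops[i]))
  }
  invisible(x)
}

#' Regional allele-frequency spectra
#'
#' For each region, loci are pooled using the region-mean allele frequency
#' (the only well-defined pooling for frequency-level data) and the
#' reference-allele frequency (unfolded) or minor-allele frequency (folded,
#' the default: SNP reference alleles are arbitrary) is tallied per locus
#' into `bins` equal-width bins on `[0, 1]` (folded: `[0, 0.5]`). Binning
#' follows the histogram convention: right-closed intervals with the first
#' bin closed on both sides. The reference allele is the first allele of
#' each locus's catalogue.
#'
#' @param ds an [afreq_dataset()]
#' @param region_map named character vector population id -> region;
#'   defaults to the dataset's location table
#' @param bins number of bins (>= 2)
#' @param folded fold the spectrum at 0.5?
#' @return an object of class `spectrum_table`: `counts` (region x bin
#'   matrix), `edges`, `locus_count` per region, `folded`
#' @export
allele_frequency_spectrum <- function(ds, region_map = NULL, bins = 10,
                                      folded = TRUE) {
  stopifnot(inherits(ds, "afreq_dataset"))
  if (bins < 2) .stopf("bins must be >= 2")
  if (is.null(region_map)) {
    if (is.null(ds$locations)) .stopf("no region map and no locations attached")
    region_map <- stats::setNames(ds$locations$region, ds$locations$id)
  }
  reg <- as.character(region_map[ds$pops])
  # factor input: keep unused levels as empty rows
  regions <- if (is.factor(region_map)) levels(region_map) else unique(region_map)
  top <- if (folded) 0.5 else 1
  edges <- seq(0, top, length.out = bins + 1)
  counts <- matrix(0L, length(regions), bins,
                   dimnames = list(regions,
                                   sprintf("(%.3g,%.3g]", edges[-(bins + 1)],
                                           edges[-1])))
  locus_count <- stats::setNames(integer(length(regions)), regions)
  for (r in regions) {
    pops_r <- ds$pops[!is.na(reg) & reg == r]
    if (!length(pops_r)) next
    vals <- vapply(ds$loci, function(l) {
      m <- ds$freq[[l]][pops_r, , drop = FALSE]
      m <- m[!apply(is.na(m), 1, any), , drop = FALSE]
      if (!nrow(m)) return(NA_real_)
      v <- mean(m[, 1])
      if (folded) min(v, 1 - v) else v
    }, 0)
    vals <- vals[!is.na(vals)]
    locus_count[r] <- length(vals)
    if (length(vals)) {
      idx <- findInterval(vals, edges, left.open = TRUE, rightmost.closed = FALSE)
      idx[idx == 0L] <- 1L          # first bin closed at 0
      idx <- pmin(idx, bins)        # values exactly at the top edge
      counts[r, ] <- counts[r, ] + tabulate(idx, nbins = bins)
    }
  }
  structure(list(counts = counts, edges = edges, locus_count = locus_count,
                 folded = folded),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("Allele-frequency spectrum (%s, %d bins)\n",
              if (x$folded) "folded" else "unfolded", ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Gene-flow connectivity graph from pairwise F_ST
#'
#' Connects every defined population pair whose multilocus F_ST is strictly
#' below `threshold` (negative estimates are clamped to 0 before the
#' comparison). Each edge carries the F_ST value and the island-model
#' migrant number `4*Ne*m` from [migrants_from_fst()]; clamped-to-zero
#' pairs get `Inf` migrants. The default threshold 0.01 corresponds to
#' roughly 99 migrants per generation.
#'
#' @param fst an `fst_matrix`
#' @param threshold strict upper F_ST bound for an edge
#' @param locations optional location table used for the GeoJSON export
#' @return an object of class `connectivity_graph`: `edges` (`data.frame`
#'   pop_a, pop_b, fst, four_nem), `threshold`, `nodes`, `locations`
#' @export
connectivity_edges <- function(fst, threshold = 0.01, locations = NULL) {
  stopifnot(inherits(fst, "fst_matrix"))
  m <- pmax(fst$fst, 0)
  idx <- which(upper.tri(m) & fst$defined & m < threshold, arr.ind = TRUE)
  edges <- data.frame(
    pop_a = fst$pops[idx[, 1]], pop_b = fst$pops[idx[, 2]],
    fst = m[idx],
    four_nem = ifelse(m[idx] > 0, 1 / m[idx] - 1, Inf),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$pop_a, edges$pop_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold, nodes = fst$pops,
                 locations = locations),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("Connectivity graph: %d populations, %d edges (F_ST < %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Island-model migrant number from F_ST
#'
#' Inverts Wright's island-model equilibrium `F_ST ~ 1 / (4*Ne*m + 1)`:
#' `4*Ne*m = 1/F_ST - 1`. An F_ST of 0.01 corresponds to about 99 migrants
#' per generation.
#'
#' @param fst_value F_ST in `(0, 1]`
#' @return the implied `4*Ne*m`
#' @export
migrants_from_fst <- function(fst_value) {
  if (any(fst_value <= 0))
    .stopf("F_ST <= 0 implies unbounded migration; migrant number undefined")
  if (any(fst_value > 1)) .stopf("F_ST must be <= 1")
  1 / fst_value - 1
}

#' Blue-to-red color gradient for per-population scalars
#'
#' Min-max standardizes the values, `v0 = (v - min) / (max - min)`, and maps
#' them to RGB `(v0, 0, 1 - v0)`: the lowest value renders blue `(0,0,1)`,
#' the highest red `(1,0,0)`. The mapping is invariant to affine transforms
#' of the input.
#'
#' @param values numeric vector with at least two distinct values
#' @param orientation `"high_red"` (default) or `"high_blue"`
#' @return a matrix with columns `r`, `g`, `b` in `[0, 1]`
#' @export
color_gradient <- function(values, orientation = c("high_red", "high_blue")) {
  orientation <- match.arg(orientation)
  rng <- range(values)
  if (diff(rng) == 0) .stopf("all values equal; color normalization undefined")
  v0 <- (values - rng[1]) / diff(rng)
  if (orientation == "high_blue") v0 <- 1 - v0
  out <- cbind(r = v0, g = 0, b = 1 - v0)
  rownames(out) <- names(values)
  out
}
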
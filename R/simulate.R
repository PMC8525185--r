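#' Default region labels for the synthetic coastline
#'
#' Seven geographic areas ordered along the simulated North Pacific rim;
#' the first is the diverged focal region.
#' @export
ketascan_regions <- function() {
  c("Japan/Korea", "Russia", "Alaskan Peninsula", "Western Alaska",
    "Yukon", "SEA/BC", "WA")
}

# region anchor segments (lat/lon start -> end) along the synthetic coastline
.REGION_ANCHORS <- list(
  "Japan/Korea"       = c(36.0, 129.5, 44.0, 145.0),
  "Russia"            = c(46.0, 143.0, 64.5, 179.5),
  "Alaskan Peninsula" = c(55.5, -162.0, 57.5, -156.0),
  "Western Alaska"    = c(58.5, -162.0, 63.5, -165.0),
  "Yukon"             = c(63.5, -160.0, 64.5, -145.0),
  "SEA/BC"            = c(58.0, -135.0, 50.0, -127.0),
  "WA"                = c(48.5, -124.5, 46.5, -124.0)
)

#' Simulate the latent population structure
#'
#' Places `J` populations at ordered positions along a one-dimensional
#' "coastline" mapped to plausible North Pacific latitudes/longitudes,
#' partitions them into contiguous regions (the first region is the
#' diverged focal region, a Japan/Korea analogue), and builds two
#' standardized latent axes: `a1`, the latitudinal-cline score
#' (standardized coastline position), and `a2`, the focal-region divergence
#' score (standardized focal indicator plus small within-region jitter).
#'
#' @param J number of populations (>= 8)
#' @param focal_fraction fraction of populations in the focal region,
#'   in (0, 0.5)
#' @param regions region label set in coastline order; the first label is
#'   the focal region
#' @param jitter_sd standard deviation of the jitter added to the focal
#'   indicator before standardizing `a2`
#' @param seed RNG seed (the structure is deterministic given the seed)
#' @return an object of class `latent_structure`: `locations` (a
#'   sampling-location `data.frame`), `region`, `a1`, `a2`, `coast_pos`,
#'   `focal_region`, `J`
#' @export
simulate_structure <- function(J, focal_fraction = 0.10,
                               regions = ketascan_regions(),
                               jitter_sd = 0.1, seed = NULL) {
  if (J < 8) .stopf("J must be >= 8")
  if (focal_fraction <= 0 || focal_fraction >= 0.5)
    .stopf("focal_fraction must be in (0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  nf <- max(1L, round(J * focal_fraction))
  rest <- length(regions) - 1L
  if (J - nf < rest)
    .stopf("J too small to populate all %d regions", length(regions))
  sizes <- c(nf, diff(round(seq(0, J - nf, length.out = rest + 1))))
  region <- rep(regions, times = sizes)
  lat <- lon <- numeric(J)
  for (r in regions) {
    idx <- which(region == r)
    anch <- .REGION_ANCHORS[[r]] %||% c(50, 180, 55, 180)
    tfrac <- if (length(idx) == 1) 0.5 else seq(0, 1, length.out = length(idx))
    lat[idx] <- anch[1] + tfrac * (anch[3] - anch[1])
    # interpolate longitude on the unwrapped circle so segments crossing the
    # antimeridian stay short
    l0 <- anch[2]; l1 <- anch[4]
    if (abs(l1 - l0) > 180) l1 <- l1 + ifelse(l1 < l0, 360, -360)
    lon[idx] <- normalize_longitude(l0 + tfrac * (l1 - l0))
  }
  locations <- data.frame(
    id = sprintf("P%03d", seq_len(J)),
    name = sprintf("site_%03d", seq_len(J)),
    latitude = lat, longitude = lon, region = region,
    stringsAsFactors = FALSE)
  a1 <- as.numeric(scale(seq_len(J)))
  focal <- as.numeric(region == regions[1])
  # the focal block sits at one end of the coastline, so the raw indicator is
  # correlated with the cline; orthogonalize so the two planted axes are
  # separately identifiable (see the methods vignette)
  a2_raw <- focal + stats::rnorm(J, 0, jitter_sd)
  a2 <- as.numeric(scale(stats::resid(stats::lm(a2_raw ~ a1))))
  structure(list(locations = locations, region = region, a1 = a1, a2 = a2,
                 coast_pos = seq_len(J), focal_region = regions[1], J = J),
            class = "latent_structure")
}

#' @export
print.latent_structure <- function(x, ...) {
  cat(sprintf("Latent structure: %d populations, %d regions (focal: %s, %d pops)\n",
              x$J, length(unique(x$region)), x$focal_region,
              sum(x$region == x$focal_region)))
  invisible(x)
}

# Calibration constants for the microsatellite generator, fixed once against
# the NC83 estimator at the default configuration (see the methods vignette):
# the cline tilt, focal tilt and drift F all scale with target_fst so the
# no-differentiation limit is exact and realized G_ST is monotone in the
# target; cHe compensates the heterozygosity lost to the structure tilt.
.MSAT_CAL <- list(c1 = 3.5, c2 = 2.4, cF = 0.5, cHe = 1.4)

#' Simulate microsatellite-like allele frequencies
#'
#' Balding-Nichols-style hierarchy. Per locus: an ancestral frequency
#' vector is drawn from a symmetric Dirichlet whose concentration is tuned
#' so the dataset-level mean expected heterozygosity comes out near
#' `mean_he_target`; each population's mean frequency vector is the
#' ancestral vector tilted on the log scale along the latent cline (`a1`)
#' and focal (`a2`) axes; the population's true frequencies are drawn from
#' a Dirichlet around that mean with concentration `(1 - F) / F`; and the
#' reported frequencies are multinomial samples of `2 * n_per_pop` gene
#' copies, renormalized. The tilt scales and `F` are proportional to
#' `target_fst` (tilts to its square root), calibrated once so the realized
#' mean pairwise NC83 G_ST tracks `target_fst` at the default configuration.
#'
#' @param ls a [simulate_structure()] result
#' @param L number of loci
#' @param alleles_per_locus alleles per locus (>= 10, microsatellite-like)
#' @param target_fst targeted mean pairwise multilocus G_ST, in (0, 0.2)
#'   (0 gives the no-differentiation limit)
#' @param mean_he_target targeted mean expected heterozygosity
#' @param n_per_pop diploid individuals sampled per population
#' @param seed RNG seed
#' @return an [afreq_dataset()] with the structure's locations attached
#' @export
simulate_msat_frequencies <- function(ls, L = 10, alleles_per_locus = 15,
                                      target_fst = 0.019,
                                      mean_he_target = 0.89,
                                      n_per_pop = 50, seed = NULL) {
  stopifnot(inherits(ls, "latent_structure"))
  if (alleles_per_locus < 10) .stopf("alleles_per_locus must be >= 10")
  if (target_fst < 0 || target_fst >= 0.2) .stopf("target_fst must be in [0, 0.2)")
  if (!is.null(seed)) set.seed(seed)
  A <- alleles_per_locus; J <- ls$J
  F_drift <- .MSAT_CAL$cF * target_fst
  s1 <- .MSAT_CAL$c1 * sqrt(target_fst)
  s2 <- .MSAT_CAL$c2 * sqrt(target_fst)
  # compensate the ancestral H_e target for drift, finite-sample and
  # structure-tilt losses so the dataset-level mean lands on mean_he_target
  shrink <- (1 - F_drift) * (1 - 1 / (2 * n_per_pop)) *
    (1 - .MSAT_CAL$cHe * target_fst)
  if (mean_he_target >= (A - 1) / A * shrink)
    .stopf("mean_he_target %.3f infeasible with %d alleles (max attainable %.3f)",
           mean_he_target, A, (A - 1) / A * shrink)
  # the compensated ancestral target is capped just below the equifrequency
  # ceiling (compensation saturates; the raw target stays attainable)
  he_anc <- min(mean_he_target / shrink, (A - 1) / A - 1e-4)
  conc_anc <- he_anc / ((1 - he_anc) * A - 1)
  freq <- vector("list", L)
  names(freq) <- sprintf("msat%02d", seq_len(L))
  for (l in seq_len(L)) {
    p_anc <- pmax(rdirichlet(1, rep(conc_anc, A))[1, ], 1e-12)
    d1 <- stats::rnorm(A); d2 <- stats::rnorm(A)
    eta <- matrix(log(p_anc), J, A, byrow = TRUE) +
      s1 * outer(ls$a1, d1) + s2 * outer(ls$a2, d2)
    mu <- exp(eta - apply(eta, 1, max))
    mu <- mu / rowSums(mu)
    ptrue <- if (F_drift < 1e-9) mu else {
      conc <- (1 - F_drift) / F_drift
      t(vapply(seq_len(J), function(j) rdirichlet(1, conc * mu[j, ])[1, ],
               numeric(A)))
    }
    cnt <- vapply(seq_len(J), function(j)
      stats::rmultinom(1, 2 * n_per_pop, pmax(ptrue[j, ], 0))[, 1], numeric(A))
    m <- t(cnt) / (2 * n_per_pop)
    dimnames(m) <- list(ls$locations$id, sprintf("a%02d", seq_len(A)))
    freq[[l]] <- m
  }
  n <- matrix(n_per_pop, J, L, dimnames = list(ls$locations$id, names(freq)))
  afreq_dataset(freq, n, ploidy = rep(2L, L), locations = ls$locations)
}

#' Simulate a SNP genotype dataset with planted outlier loci
#'
#' Inverts the selection-scan regression model as a generator: for locus
#' `i` and population `j`,
#' `logit(p_ji) = logit(p0_i) + b1_i * a1_j + b2_i * a2_j`, with neutral
#' loci drawing `b1, b2 ~ N(0, neutral_sd^2)` and outlier loci drawing
#' `|b2| ~ U(effect_scale, 2 * effect_scale)` (random sign). Individual
#' genotypes are `Binomial(2, p_ji)` (Hardy-Weinberg sampling).
#'
#' With `ascertainment = "focal-discovery"`, any locus whose mean
#' minor-allele frequency in the discovery region falls below `maf_min` is
#' discarded and redrawn, emulating SNP-panel discovery concentrated in one
#' region; this inflates expected heterozygosity there.
#'
#' @param ls a [simulate_structure()] result
#' @param L_neutral number of neutral loci (>= 10)
#' @param L_outlier number of planted outlier loci (>= 1; 0 allowed for
#'   null simulations)
#' @param n_per_pop diploid individuals per population
#' @param effect_scale lower bound of the planted `|b2|` (logit scale)
#' @param neutral_sd standard deviation of neutral `b1`, `b2`
#' @param ascertainment `"off"` or `"focal-discovery"`
#' @param discovery_region region whose minor-allele frequencies gate locus
#'   discovery (default `"Western Alaska"`)
#' @param maf_min discovery minor-allele-frequency cut
#' @param seed RNG seed
#' @return a list with `genotypes` (a [genotype_dataset()]) and `truth`
#'   (a `data.frame`: locus, p0, b1, b2, is_outlier; the generator
#'   configuration is attached as attribute `"config"`)
#' @export
simulate_snp_dataset <- function(ls, L_neutral = 50, L_outlier = 5,
                                 n_per_pop = 50, effect_scale = 3,
                                 neutral_sd = 0.3,
                                 ascertainment = c("off", "focal-discovery"),
                                 discovery_region = "Western Alaska",
                                 maf_min = 0.05, seed = NULL) {
  stopifnot(inherits(ls, "latent_structure"))
  ascertainment <- match.arg(ascertainment)
  if (L_neutral < 10) .stopf("L_neutral must be >= 10")
  if (L_outlier < 0) .stopf("L_outlier must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (ascertainment == "focal-discovery" &&
      !discovery_region %in% ls$region)
    .stopf("discovery region '%s' has no populations", discovery_region)
  L <- L_neutral + L_outlier
  disc <- which(ls$region == discovery_region)
  is_outlier <- c(rep(FALSE, L_neutral), rep(TRUE, L_outlier))
  truth <- data.frame(locus = sprintf("snp%03d", seq_len(L)),
                      p0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                      is_outlier = is_outlier, stringsAsFactors = FALSE)
  pmat <- matrix(NA_real_, ls$J, L)
  attempts <- 0L
  for (i in seq_len(L)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1000L * L)
        .stopf("ascertainment filter rejected too many loci (infeasible)")
      # Beta(0.6, 0.6) ancestral frequencies give the moderate panel-level
      # SNP heterozygosity (E[2p(1-p)] ~ 0.27) typical of GSI SNP baselines
      p0 <- min(max(stats::rbeta(1, 0.6, 0.6), 0.02), 0.98)
      b1 <- stats::rnorm(1, 0, neutral_sd)
      b2 <- if (is_outlier[i]) {
        sample(c(-1, 1), 1) * stats::runif(1, effect_scale, 2 * effect_scale)
      } else stats::rnorm(1, 0, neutral_sd)
      p <- stats::plogis(stats::qlogis(p0) + b1 * ls$a1 + b2 * ls$a2)
      if (ascertainment == "focal-discovery") {
        m <- mean(p[disc])
        if (min(m, 1 - m) < maf_min) next
      }
      truth$p0[i] <- p0; truth$b1[i] <- b1; truth$b2[i] <- b2
      pmat[, i] <- p
      break
    }
  }
  genotypes <- lapply(seq_len(ls$J), function(j) {
    g2 <- matrix(stats::rbinom(n_per_pop * L, 2, rep(pmat[j, ], each = n_per_pop)),
                 n_per_pop, L)  # copies of allele 2 per individual
    arr <- array(0L, dim = c(n_per_pop, L, 2L),
                 dimnames = list(sprintf("%s_%03d", ls$locations$id[j],
                                         seq_len(n_per_pop)),
                                 truth$locus, c("a1", "a2")))
    arr[, , 1L] <- ifelse(g2 >= 1L, 2L, 1L)
    arr[, , 2L] <- ifelse(g2 == 2L, 2L, 1L)
    arr
  })
  names(genotypes) <- ls$locations$id
  gd <- genotype_dataset(genotypes, truth$locus, locations = ls$locations)
  attr(truth, "config") <- list(L_neutral = L_neutral, L_outlier = L_outlier,
                                n_per_pop = n_per_pop,
                                effect_scale = effect_scale,
                                neutral_sd = neutral_sd,
                                ascertainment = ascertainment,
                                discovery_region = discovery_region,
                                maf_min = maf_min, seed = seed)
  list(genotypes = gd, truth = truth)
}

#' Simulate a multi-allelic haploid (mtDNA-like) locus
#'
#' The major allele sits near `background_major_freq` outside the focal
#' region and near `focal_major_freq` inside it (Normal jitter, clipped to
#' `[0, 1]`); the remaining mass is spread over the minor alleles with
#' population-specific Dirichlet weights. The major allele is listed
#' second in the allele catalogue, mirroring haplotype tables where the
#' dominant haplotype is not the first-listed allele.
#'
#' @param ls a [simulate_structure()] result
#' @param n_alleles number of alleles (>= 2)
#' @param focal_major_freq mean major-allele frequency inside the focal
#'   region
#' @param background_major_freq major-allele frequency elsewhere
#' @param jitter_sd focal-region jitter standard deviation
#' @param n_per_pop haplotypes sampled per population
#' @param locus_name locus label
#' @param seed RNG seed
#' @return a single-locus haploid [afreq_dataset()]
#' @export
simulate_mtdna_locus <- function(ls, n_alleles = 5, focal_major_freq = 0.21,
                                 background_major_freq = 0.98,
                                 jitter_sd = 0.11, n_per_pop = 50,
                                 locus_name = "mtDNA3", seed = NULL) {
  stopifnot(inherits(ls, "latent_structure"))
  if (n_alleles < 2) .stopf("n_alleles must be >= 2")
  if (focal_major_freq <= 0 || focal_major_freq >= background_major_freq ||
      background_major_freq > 1)
    .stopf("need 0 < focal_major_freq < background_major_freq <= 1")
  if (!is.null(seed)) set.seed(seed)
  J <- ls$J
  focal <- ls$region == ls$focal_region
  major <- ifelse(focal,
                  pmin(pmax(stats::rnorm(J, focal_major_freq, jitter_sd), 0), 1),
                  background_major_freq)
  minors <- rdirichlet(J, rep(1, n_alleles - 1)) * (1 - major)
  # major allele second in the catalogue
  m <- cbind(minors[, 1, drop = FALSE], major,
             if (n_alleles > 2) minors[, -1, drop = FALSE])
  m <- m / rowSums(m)
  dimnames(m) <- list(ls$locations$id, sprintf("h%d", seq_len(n_alleles)))
  freq <- stats::setNames(list(m), locus_name)
  n <- matrix(n_per_pop, J, 1, dimnames = list(ls$locations$id, locus_name))
  afreq_dataset(freq, n, ploidy = 1L, locations = ls$locations)
}

#' Combine allele-frequency datasets over loci
#'
#' Binds the loci of two datasets sharing the same population set, e.g. the
#' nuclear SNP panel with the mtDNA-like haploid locus.
#'
#' @param a,b [afreq_dataset()] objects with identical populations
#' @return an [afreq_dataset()] with the loci of both
#' @export
merge_afreq_loci <- function(a, b) {
  stopifnot(inherits(a, "afreq_dataset"), inherits(b, "afreq_dataset"))
  if (!identical(a$pops, b$pops)) .stopf("datasets must share the same populations")
  if (any(b$loci %in% a$loci)) .stopf("duplicate locus names across datasets")
  het <- NULL
  if (!is.null(a$het) || !is.null(b$het)) {
    blank <- function(ds) matrix(NA_real_, length(ds$pops), length(ds$loci),
                                 dimnames = list(ds$pops, ds$loci))
    het <- cbind(a$het %||% blank(a), b$het %||% blank(b))
  }
  afreq_dataset(c(a$freq, b$freq), cbind(a$n, b$n),
                ploidy = c(a$ploidy, b$ploidy),
                locations = a$locations %||% b$locations, het = het)
}
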
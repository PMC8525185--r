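#' Allele-frequency dataset
#'
#' The central container for frequency-level data: for every population x
#' locus combination it stores a frequency vector over the locus's allele
#' catalogue plus a sample size (diploid individuals for nuclear loci,
#' haplotypes for haploid loci). Combinations with no data are "absent":
#' an all-`NA` frequency row and an `NA` sample size.
#'
#' @param freq named list, one element per locus: a `J x A` numeric matrix
#'   of allele frequencies with populations as rows (rownames required) and
#'   alleles as columns (colnames required). A fully-`NA` row marks the
#'   population x locus combination absent.
#' @param n `J x L` matrix of sample sizes (rownames populations, colnames
#'   loci); `NA` where absent.
#' @param ploidy integer vector, 1 or 2 per locus (named or in locus order).
#'   Defaults to 2 for every locus.
#' @param locations optional `data.frame` of sampling locations as returned by
#'   [read_locations()], with `id` matching the population names.
#' @param het optional `J x L` matrix of observed heterozygosities (available
#'   when the dataset was derived from genotypes); used by
#'   [pairwise_fst()] with `ho_mode = "observed"`.
#'
#' @return an object of class `afreq_dataset` with elements `pops`, `loci`,
#'   `alleles`, `freq`, `n`, `ploidy`, `locations`, `het`.
#' @export
afreq_dataset <- function(freq, n, ploidy = NULL, locations = NULL, het = NULL) {
  if (!is.list(freq) || is.null(names(freq)) || !length(freq))
    .stopf("'freq' must be a non-empty named list of per-locus matrices")
  loci <- names(freq)
  pops <- rownames(freq[[1]])
  if (is.null(pops)) .stopf("frequency matrices must have population rownames")
  for (l in loci) {
    m <- freq[[l]]
    if (!is.matrix(m) || !identical(rownames(m), pops))
      .stopf("locus '%s': frequency matrix rows must match the population set", l)
    if (is.null(colnames(m))) .stopf("locus '%s': allele names (colnames) required", l)
    present <- !apply(is.na(m), 1, all)
    if (any(is.na(m[present, , drop = FALSE])))
      .stopf("locus '%s': partially missing frequency vector", l)
    if (any(m[present, , drop = FALSE] < -1e-12))
      .stopf("locus '%s': negative allele frequency", l)
    s <- rowSums(m[present, , drop = FALSE])
    if (length(s) && any(abs(s - 1) > 1e-9))
      .stopf("locus '%s': frequency vector does not sum to 1 (max deviation %.3g)",
             l, max(abs(s - 1)))
  }
  n <- as.matrix(n)
  if (!identical(rownames(n), pops) || !identical(colnames(n), loci))
    .stopf("'n' must be a population x locus matrix matching 'freq'")
  if (any(!is.na(n) & (n <= 0 | abs(n - round(n)) > 1e-8)))
    .stopf("sample sizes must be positive integers")
  if (is.null(ploidy)) ploidy <- rep(2L, length(loci))
  if (is.null(names(ploidy))) names(ploidy) <- loci
  ploidy <- as.integer(ploidy[loci])
  names(ploidy) <- loci
  if (any(!ploidy %in% c(1L, 2L))) .stopf("ploidy must be 1 or 2 per locus")
  if (!is.null(locations)) {
    if (!all(pops %in% locations$id))
      .stopf("locations must cover every population id")
    locations <- locations[match(pops, locations$id), , drop = FALSE]
    rownames(locations) <- NULL
  }
  structure(list(pops = pops, loci = loci,
                 alleles = lapply(freq, colnames),
                 freq = freq, n = n, ploidy = ploidy,
                 locations = locations, het = het),
            class = "afreq_dataset")
}

#' @export
print.afreq_dataset <- function(x, ...) {
  cat(sprintf("Allele-frequency dataset: %d populations, %d loci\n",
              length(x$pops), length(x$loci)))
  na <- lengths(x$alleles)
  cat(sprintf("  alleles per locus: %d-%d (median %g)\n",
              min(na), max(na), stats::median(na)))
  cat(sprintf("  ploidy: %s\n",
              paste(unique(x$ploidy), collapse = "/")))
  absent <- sum(is.na(x$n))
  if (absent) cat(sprintf("  absent population x locus combinations: %d\n", absent))
  if (!is.null(x$locations)) cat("  sampling locations attached\n")
  invisible(x)
}

#' Genotype dataset
#'
#' Diploid (or haploid) multilocus genotypes organised by population, the
#' in-memory image of a genepop file. Allele codes are positive integers;
#' 0 means missing. A genotype with either allele coded 0 is treated as
#' fully missing.
#'
#' @param genotypes named list, one element per population: an
#'   `individuals x loci x 2` integer array (dimnames: individual, locus,
#'   `c("a1","a2")`). Haploid loci use slice `a1` with `a2 = NA`.
#' @param loci character vector of locus names, the array column order.
#' @param ploidy integer 1/2 per locus, default all 2.
#' @param locations optional sampling-location `data.frame` with `id`
#'   matching population names.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, loci, ploidy = NULL, locations = NULL) {
  if (!is.list(genotypes) || is.null(names(genotypes)) || !length(genotypes))
    .stopf("'genotypes' must be a non-empty named list (one array per population)")
  if (!length(loci)) .stopf("at least one locus required")
  if (anyDuplicated(names(genotypes))) .stopf("duplicate population names")
  for (p in names(genotypes)) {
    g <- genotypes[[p]]
    if (!is.array(g) || length(dim(g)) != 3L || dim(g)[2] != length(loci) ||
        dim(g)[3] != 2L)
      .stopf("population '%s': genotype array must be individuals x %d loci x 2",
             p, length(loci))
    if (any(g < 0, na.rm = TRUE)) .stopf("population '%s': negative allele code", p)
  }
  if (is.null(ploidy)) ploidy <- rep(2L, length(loci))
  if (is.null(names(ploidy))) names(ploidy) <- loci
  ploidy <- stats::setNames(as.integer(ploidy[loci]), loci)
  if (any(!ploidy %in% c(1L, 2L))) .stopf("ploidy must be 1 or 2 per locus")
  pops <- names(genotypes)
  if (!is.null(locations)) {
    if (!all(pops %in% locations$id)) .stopf("locations must cover every population")
    locations <- locations[match(pops, locations$id), , drop = FALSE]
    rownames(locations) <- NULL
  }
  structure(list(pops = pops, loci = as.character(loci), ploidy = ploidy,
                 genotypes = genotypes, locations = locations),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ni <- vapply(x$genotypes, function(g) dim(g)[1], 0L)
  cat(sprintf("Genotype dataset: %d populations, %d loci, %d individuals\n",
              length(x$pops), length(x$loci), sum(ni)))
  invisible(x)
}
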
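#' Read a genepop file
#'
#' Parses the standard genepop text layout: a title line, the locus names
#' (comma-separated and/or one per line), then population blocks separated
#' by a line reading `pop` (case-insensitive), each individual on a line
#' `label , g1 g2 ...` with 2- or 3-digit allele codes concatenated per
#' diploid genotype. An all-zero genotype (`0000`/`000000`) is missing;
#' a half-called genotype (one allele 0) is conservatively treated as
#' fully missing too.
#'
#' Following the genepop convention, each population is named after the
#' label of the *last* individual in its block; `pop_names` overrides this.
#'
#' @param path path to a genepop file
#' @param allele_digits 2, 3 or `"auto"` (detect from the first genotype)
#' @param pop_names optional character vector of population names, one per
#'   block in file order
#' @return a [genotype_dataset()]
#' @export
read_genepop <- function(path, allele_digits = "auto", pop_names = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 3) .stopf("genepop file too short: %s", path)
  is_pop <- vapply(lines, function(x) tolower(trimws(x)) == "pop", TRUE,
                   USE.NAMES = FALSE)
  pop_at <- which(is_pop)
  if (!length(pop_at)) .stopf("no 'pop' separator found: zero populations")
  if (pop_at[1] < 3) .stopf("no locus lines before the first 'pop' separator")
  locus_lines <- lines[2:(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) .stopf("zero loci declared")
  if (anyDuplicated(loci)) .stopf("duplicate locus names in header")
  L <- length(loci)

  digits <- NA_integer_
  if (!identical(allele_digits, "auto")) {
    digits <- as.integer(allele_digits)
    if (!digits %in% c(2L, 3L)) .stopf("allele_digits must be 2, 3 or \"auto\"")
  }

  starts <- pop_at
  ends <- c(pop_at[-1] - 1L, length(lines))
  genotypes <- list()
  blk_names <- character(0)
  for (b in seq_along(starts)) {
    rows <- (starts[b] + 1L):ends[b]
    rows <- rows[nzchar(trimws(lines[rows]))]
    if (!length(rows)) .stopf("empty population block %d", b)
    labels <- character(length(rows))
    arr <- array(NA_integer_, dim = c(length(rows), L, 2L))
    for (i in seq_along(rows)) {
      ln <- rows[i]
      txt <- lines[ln]
      cm <- regexpr(",", txt, fixed = TRUE)
      if (cm < 0) .stopf("line %d: individual line lacks the 'label ,' comma", ln)
      labels[i] <- trimws(substr(txt, 1, cm - 1))
      codes <- strsplit(trimws(substr(txt, cm + 1, nchar(txt))), "[ \t]+")[[1]]
      codes <- codes[nzchar(codes)]
      if (length(codes) != L)
        .stopf("line %d: expected %d genotypes, found %d", ln, L, length(codes))
      if (is.na(digits)) {
        w <- nchar(codes[1])
        if (!w %in% c(4L, 6L))
          .stopf("line %d: cannot infer allele digits from genotype width %d", ln, w)
        digits <- w %/% 2L
      }
      if (any(nchar(codes) != 2L * digits))
        .stopf("line %d: malformed genotype width (expected %d characters)",
               ln, 2L * digits)
      if (any(grepl("[^0-9]", codes)))
        .stopf("line %d: non-numeric allele code", ln)
      a1 <- as.integer(substr(codes, 1L, digits))
      a2 <- as.integer(substr(codes, digits + 1L, 2L * digits))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- 0L; a2[miss] <- 0L
      arr[i, , 1L] <- a1
      arr[i, , 2L] <- a2
    }
    dimnames(arr) <- list(make.unique(labels), loci, c("a1", "a2"))
    nm <- if (!is.null(pop_names)) pop_names[b] else labels[length(labels)]
    blk_names <- c(blk_names, nm)
    genotypes[[b]] <- arr
  }
  if (anyDuplicated(blk_names)) blk_names <- make.unique(blk_names)
  names(genotypes) <- blk_names
  genotype_dataset(genotypes, loci)
}

#' Write a genotype dataset in genepop format
#'
#' The output round-trips through [read_genepop()] with identical allele
#' counts. Individuals are labelled with their population name so that the
#' last-individual naming convention recovers the population names.
#'
#' @param ds a [genotype_dataset()] (diploid loci only)
#' @param path output file path
#' @param allele_digits 2 or 3; every allele code must be `< 10^allele_digits`
#' @param title first (comment) line of the file
#' @return `path`, invisibly
#' @export
write_genepop <- function(ds, path, allele_digits = 3, title = "ketascan export") {
  stopifnot(inherits(ds, "genotype_dataset"))
  digits <- as.integer(allele_digits)
  if (!digits %in% c(2L, 3L)) .stopf("allele_digits must be 2 or 3")
  if (!length(ds$loci)) .stopf("dataset has no loci")
  if (any(ds$ploidy != 2L))
    .stopf("genepop output supports diploid loci only")
  mx <- max(0L, unlist(lapply(ds$genotypes, function(g) max(g, 0L, na.rm = TRUE))))
  if (mx >= 10^digits)
    .stopf("allele code %d does not fit in %d digits; no silent truncation", mx, digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (p in ds$pops) {
    writeLines("pop", con)
    g <- ds$genotypes[[p]]
    for (i in seq_len(dim(g)[1])) {
      a1 <- g[i, , 1L]; a2 <- g[i, , 2L]
      a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
      codes <- sprintf("%0*d%0*d", digits, a1, digits, a2)
      writeLines(sprintf("%s ,  %s", p, paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Convert genotypes to allele frequencies
#'
#' Per population x locus: frequency = allele count / (ploidy x non-missing
#' individuals); the recorded sample size is the number of non-missing
#' individuals. Combinations with zero non-missing individuals are flagged
#' absent. Observed heterozygosity is computed alongside (diploid loci) and
#' attached for use by [pairwise_fst()]'s `ho_mode = "observed"`.
#'
#' @param ds a [genotype_dataset()]
#' @return an [afreq_dataset()]
#' @export
genotypes_to_frequencies <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  J <- length(ds$pops); L <- length(ds$loci)
  # allele catalogue per locus: sorted unique non-zero codes over all pops
  catalog <- lapply(seq_len(L), function(l) {
    codes <- unlist(lapply(ds$genotypes, function(g) g[, l, ]))
    sort(unique(codes[!is.na(codes) & codes > 0L]))
  })
  names(catalog) <- ds$loci
  n <- matrix(NA_real_, J, L, dimnames = list(ds$pops, ds$loci))
  het <- matrix(NA_real_, J, L, dimnames = list(ds$pops, ds$loci))
  freq <- vector("list", L); names(freq) <- ds$loci
  for (l in seq_len(L)) {
    al <- catalog[[l]]
    if (!length(al)) al <- 1L  # all-missing locus everywhere: keep a dummy column
    m <- matrix(NA_real_, J, length(al),
                dimnames = list(ds$pops, as.character(al)))
    hap <- ds$ploidy[l] == 1L
    for (j in seq_len(J)) {
      g <- ds$genotypes[[ds$pops[j]]]
      a1 <- g[, l, 1L]; a2 <- g[, l, 2L]
      if (hap) {
        ok <- !is.na(a1) & a1 > 0L
        if (!any(ok)) next
        cnt <- tabulate(match(a1[ok], al), nbins = length(al))
        m[j, ] <- cnt / sum(cnt)
        n[j, l] <- sum(ok)
      } else {
        ok <- !is.na(a1) & !is.na(a2) & a1 > 0L & a2 > 0L
        if (!any(ok)) next
        cnt <- tabulate(match(a1[ok], al), nbins = length(al)) +
               tabulate(match(a2[ok], al), nbins = length(al))
        m[j, ] <- cnt / sum(cnt)
        n[j, l] <- sum(ok)
        het[j, l] <- mean(a1[ok] != a2[ok])
      }
    }
    freq[[l]] <- m
  }
  afreq_dataset(freq, n, ploidy = ds$ploidy, locations = ds$locations, het = het)
}
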
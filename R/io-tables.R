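#' Read a long-format allele-frequency table
#'
#' Expects delimited text with columns `population_id`, `locus`, `allele`,
#' `frequency`, `sample_size` (one row per population x locus x allele).
#' The long layout accommodates ragged allele catalogues (microsatellites
#' next to SNPs). Frequency vectors whose sum deviates from 1 by at most
#' `1e-6` are renormalized; larger deviations are validation errors naming
#' the offending population x locus.
#'
#' @param path input file
#' @param sep field separator (default `","`; use `"\t"` for TSV)
#' @param ploidy 1 or 2, recycled per locus (2 = diploid individuals,
#'   1 = haploid haplotypes as the sample-size unit)
#' @param locations optional sampling-location table to attach
#' @return an [afreq_dataset()]
#' @export
read_frequency_table <- function(path, sep = ",", ploidy = 2, locations = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character", "character",
                                         "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("population_id", "locus", "allele", "frequency", "sample_size")
  if (!all(need %in% names(df)))
    .stopf("frequency table must have columns: %s", paste(need, collapse = ", "))
  if (any(df$frequency < 0))
    .stopf("negative frequency at row %d", which(df$frequency < 0)[1])
  pops <- unique(df$population_id)
  loci <- unique(df$locus)
  n <- matrix(NA_real_, length(pops), length(loci), dimnames = list(pops, loci))
  freq <- vector("list", length(loci)); names(freq) <- loci
  for (l in loci) {
    dl <- df[df$locus == l, , drop = FALSE]
    alleles <- unique(dl$allele)
    m <- matrix(NA_real_, length(pops), length(alleles),
                dimnames = list(pops, alleles))
    for (p in unique(dl$population_id)) {
      dp <- dl[dl$population_id == p, , drop = FALSE]
      if (anyDuplicated(dp$allele))
        .stopf("duplicate allele rows for population '%s', locus '%s'", p, l)
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      v[dp$allele] <- dp$frequency
      s <- sum(v)
      if (abs(s - 1) > 1e-6)
        .stopf("frequencies for population '%s', locus '%s' sum to %.8f (not 1)",
               p, l, s)
      # renormalize only when needed: exact values stay byte-stable
      m[p, ] <- if (abs(s - 1) > 1e-12) v / s else v
      sz <- unique(dp$sample_size)
      if (length(sz) != 1)
        .stopf("inconsistent sample_size for population '%s', locus '%s'", p, l)
      n[p, l] <- sz
    }
    freq[[l]] <- m
  }
  afreq_dataset(freq, n, ploidy = rep(ploidy, length.out = length(loci)),
                locations = locations)
}

#' Write an allele-frequency dataset as a long-format table
#'
#' Rows are emitted in canonical order (population, then locus, then allele,
#' each in dataset order), so write-then-read-then-write is byte-stable.
#' Absent population x locus combinations are omitted.
#'
#' @param ds an [afreq_dataset()]
#' @param path output file
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_frequency_table <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "afreq_dataset"))
  rows <- list()
  for (p in ds$pops) for (l in ds$loci) {
    v <- ds$freq[[l]][p, ]
    if (all(is.na(v))) next
    rows[[length(rows) + 1L]] <- data.frame(
      population_id = p, locus = l, allele = names(v),
      frequency = as.numeric(v), sample_size = ds$n[p, l],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sampling-location table
#'
#' Tab-separated text with header `id`, `name`, `latitude`, `longitude`,
#' `region`. Coordinates are decimal degrees (WGS84 assumed); longitudes are
#' normalized to `(-180, 180]` so that distances across the antimeridian
#' (Russia vs Alaska) stay correct.
#'
#' @param path input file
#' @param sep field separator, default tab
#' @return a `data.frame` of locations in file order
#' @export
read_locations <- function(path, sep = "\t") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("id", "name", "latitude", "longitude", "region")
  if (!all(need %in% names(df)))
    .stopf("location table must have columns: %s", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$latitude) | df$latitude < -90 | df$latitude > 90)
  if (length(bad)) .stopf("latitude out of [-90, 90] at row %d", bad[1])
  bad <- which(!is.finite(df$longitude))
  if (length(bad)) .stopf("non-finite longitude at row %d", bad[1])
  dup <- which(duplicated(df$id))
  if (length(dup)) .stopf("duplicate location id '%s' at row %d", df$id[dup[1]], dup[1])
  df$longitude <- normalize_longitude(df$longitude)
  df[, need]
}

#' Write a sampling-location table
#' @param locations a location `data.frame` (see [read_locations()])
#' @param path output file
#' @param sep field separator, default tab
#' @return `path`, invisibly
#' @export
write_locations <- function(locations, path, sep = "\t") {
  utils::write.table(locations, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a tree to newick text
#'
#' Branch lengths are written at full precision (including `:0` for
#' zero-length branches) with a terminating semicolon; the text re-parses
#' with [ape::read.tree()] to the identical topology and lengths.
#'
#' @param tree an [ape::phylo] object
#' @param path optional file; when `NULL` the newick string is returned
#' @return newick string (invisibly when writing to a file)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    .stopf("negative branch length")
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
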
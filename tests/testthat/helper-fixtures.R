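# Programmatic fixtures; everything is generated at test time.

random_genotype_dataset <- function(J = 3, L = 5, n = 6, max_allele = 8,
                                    missing = TRUE, seed = 1) {
  set.seed(seed)
  loci <- sprintf("loc%02d", seq_len(L))
  gl <- lapply(seq_len(J), function(j) {
    arr <- array(sample.int(max_allele, n * L * 2, replace = TRUE),
                 dim = c(n, L, 2))
    if (missing && stats::runif(1) < 0.7) {
      for (z in seq_len(sample(1:2, 1))) {
        arr[sample(n, 1), sample(L, 1), ] <- 0L
      }
    }
    storage.mode(arr) <- "integer"
    dimnames(arr) <- list(sprintf("ind%02d", seq_len(n)), loci, c("a1", "a2"))
    arr
  })
  names(gl) <- sprintf("POP%02d", seq_len(J))
  genotype_dataset(gl, loci)
}

# brute-force per-population tally, independent of genotypes_to_frequencies
tally_oracle <- function(gd, pop, locus) {
  g <- gd$genotypes[[pop]]
  l <- match(locus, gd$loci)
  a1 <- g[, l, 1]; a2 <- g[, l, 2]
  ok <- a1 > 0 & a2 > 0
  codes <- c(a1[ok], a2[ok])
  list(counts = table(codes), n = sum(ok))
}

make_locations <- function(ids, names = ids, lat, lon, region = "R") {
  data.frame(id = ids, name = names, latitude = lat, longitude = lon,
             region = rep_len(region, length(ids)), stringsAsFactors = FALSE)
}

# hand-built afreq dataset from a list of per-locus matrices
quick_afreq <- function(freq, n_per_pop = 10, ploidy = NULL, locations = NULL) {
  pops <- rownames(freq[[1]])
  n <- matrix(n_per_pop, length(pops), length(freq),
              dimnames = list(pops, names(freq)))
  for (l in names(freq)) n[apply(is.na(freq[[l]]), 1, all), l] <- NA
  afreq_dataset(freq, n, ploidy = ploidy, locations = locations)
}

# hand-built fst_matrix for graph tests
quick_fst <- function(m, pops = NULL) {
  if (is.null(pops)) pops <- rownames(m)
  if (is.null(pops)) pops <- paste0("P", seq_len(nrow(m)))
  dimnames(m) <- list(pops, pops)
  structure(list(fst = m, defined = !is.na(m), pops = pops,
                 loci = "synthetic", per_locus = NULL,
                 ho_mode = "hwe", combine = "ratio_of_sums"),
            class = "fst_matrix")
}
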
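test_that("location matching prefers exact names, then nearest, with id tie-break", {
  msat <- make_locations(c("M1", "M2", "A2", "A1"),
                         names = c("chitose", "tokachi", "east", "west"),
                         lat = c(42.8, 42.9, 60, 60),
                         lon = c(141.6, 143.3, -150.1, -160))
  snp <- make_locations("S1", names = "Chitose", lat = 43.0, lon = 141.0)
  m <- match_locations(snp, msat)
  expect_equal(m$msat_id, "M1")
  expect_equal(m$match_type, "exact-name")
  expect_gt(m$distance_km, 0)
  expect_equal(m$distance_km,
               haversine_oracle(43.0, 141.0, 42.8, 141.6), tolerance = 1e-9)

  # nearest by haversine
  snp2 <- make_locations("S2", names = "nowhere", lat = 60, lon = -150)
  m2 <- match_locations(snp2, msat)
  expect_equal(m2$msat_id, "A2")
  expect_equal(m2$match_type, "nearest")
  expect_equal(m2$distance_km, haversine_oracle(60, -150, 60, -150.1),
               tolerance = 1e-9)

  # equidistant candidates resolve to the lexicographically smallest id
  tie <- make_locations(c("A2", "A1"), names = c("x", "y"),
                        lat = c(10, 10), lon = c(1, -1))
  snp3 <- make_locations("S3", names = "z", lat = 10, lon = 0)
  expect_equal(match_locations(snp3, tie)$msat_id, "A1")
  expect_error(match_locations(snp3[0, ], tie), "non-empty")
})

test_that("every query site gets exactly one match on asymmetric site lists", {
  set.seed(71)
  big <- make_locations(sprintf("M%03d", 1:120), lat = runif(120, 40, 65),
                        lon = runif(120, 130, 180))
  small <- make_locations(sprintf("S%02d", 1:35),
                          names = c(big$name[1:10], sprintf("new%02d", 1:25)),
                          lat = runif(35, 40, 65), lon = runif(35, 130, 180))
  m <- match_locations(small, big)
  expect_equal(nrow(m), 35)
  expect_false(anyNA(m$msat_id))
  expect_equal(sum(m$match_type == "exact-name"), 10)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 6)), rep(1, 6))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(81)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # ties included
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("locus regression reproduces hand-solved normal equations", {
  # noise-free plane is interpolated exactly
  set.seed(91)
  mds1 <- rnorm(12); mds2 <- rnorm(12)
  p <- 0.3 + 0.2 * mds1 - 0.4 * mds2
  # lm flags the noise-free interpolation as an "essentially perfect fit"
  r <- suppressWarnings(regress_locus(p, mds1, mds2))
  expect_equal(c(r$b0, r$b1, r$b2), c(0.3, 0.2, -0.4), tolerance = 1e-10)
  expect_lt(r$sigma2, 1e-20)
  # 5-point hand dataset against the normal-equation oracle
  y <- c(0.2, 0.5, 0.4, 0.9, 0.1)
  x1 <- c(-1, 0, 1, 2, -2); x2 <- c(0.5, -0.3, 0.2, -1, 0.8)
  r2 <- regress_locus(y, x1, x2)
  o <- ols_oracle(y, x1, x2)
  expect_equal(c(r2$b0, r2$b1, r2$b2), o$b, tolerance = 1e-10)
  expect_equal(c(r2$se0, r2$se1, r2$se2), o$se, tolerance = 1e-10)
  expect_equal(c(r2$p0, r2$p1, r2$p2), o$p, tolerance = 1e-10)
  expect_equal(r2$sigma2, o$s2, tolerance = 1e-12)
  # constant response: zero slopes, p-values 1
  rc <- regress_locus(rep(0.4, 8), rnorm(8), rnorm(8))
  expect_equal(c(rc$b1, rc$b2), c(0, 0))
  expect_equal(c(rc$p1, rc$p2), c(1, 1))
  # degenerate designs error
  expect_error(regress_locus(y, x1, 2 * x1), "rank-deficient|collinear")
  expect_error(regress_locus(y[1:3], x1[1:3], x2[1:3]), "at least 4")
})

test_that("OLS equals the oracle across random small designs", {
  set.seed(101)
  for (i in 1:100) {
    J <- sample(5:30, 1)
    x1 <- rnorm(J); x2 <- rnorm(J)
    y <- runif(1) + rnorm(1) * x1 + rnorm(1) * x2 + rnorm(J, 0, 0.1)
    r <- regress_locus(y, x1, x2)
    o <- ols_oracle(y, x1, x2)
    expect_equal(c(r$b0, r$b1, r$b2), o$b, tolerance = 1e-10)
    expect_equal(c(r$p0, r$p1, r$p2), o$p, tolerance = 1e-10)
  }
})

test_that("scan ranks loci by |b2|, applies BH per family, honors top_k", {
  ls <- simulate_structure(40, seed = 6)
  msat <- simulate_msat_frequencies(ls, seed = 7)
  mds <- suppressWarnings(classical_mds(pairwise_fst(msat), k = 2))
  sim <- simulate_snp_dataset(ls, L_neutral = 15, L_outlier = 3, seed = 8)
  fr <- genotypes_to_frequencies(sim$genotypes)
  sc <- scan_loci(fr, mds, top_k = 3)
  expect_equal(nrow(sc$records), 18)
  expect_true(all(diff(sc$records$abs_b2) <= 0))
  expect_true(all(sc$records$q1 >= sc$records$p1 - 1e-15))
  expect_true(all(sc$records$q2 >= sc$records$p2 - 1e-15))
  expect_equal(sc$records$q2, benjamini_hochberg(sc$records$p2))
  expect_lte(length(sc$outliers), 3)
  # top_k = 0: empty outlier set, full table retained
  sc0 <- scan_loci(fr, mds, top_k = 0)
  expect_length(sc0$outliers, 0)
  expect_equal(nrow(sc0$records), 18)
  # pooled family is exposed and changes q-values, not coefficients
  scp <- scan_loci(fr, mds, top_k = 3, bh_family = "pooled")
  expect_equal(scp$records$b2, sc$records$b2)
  expect_false(isTRUE(all.equal(scp$records$q2, sc$records$q2)))
})

test_that("scan ranking is invariant to affine rescaling of the axes", {
  ls <- simulate_structure(30, seed = 16)
  msat <- simulate_msat_frequencies(ls, seed = 17)
  mds <- suppressWarnings(classical_mds(pairwise_fst(msat), k = 2))
  sim <- simulate_snp_dataset(ls, L_neutral = 12, L_outlier = 2, seed = 18)
  fr <- genotypes_to_frequencies(sim$genotypes)
  sc1 <- scan_loci(fr, mds, top_k = 2)
  mds2 <- mds
  mds2$points <- sweep(mds$points, 2, c(2.5, 0.4), "*")
  sc2 <- scan_loci(fr, mds2, top_k = 2)
  expect_equal(sc2$records$locus, sc1$records$locus)
  expect_equal(sc2$records$b2 * 0.4, sc1$records$b2, tolerance = 1e-10)
  expect_equal(sc2$records$p2, sc1$records$p2, tolerance = 1e-10)
})

test_that("loci with excessive missingness are excluded with a warning", {
  ls <- simulate_structure(12, seed = 26)
  msat <- simulate_msat_frequencies(ls, seed = 27)
  mds <- suppressWarnings(classical_mds(pairwise_fst(msat), k = 2))
  sim <- simulate_snp_dataset(ls, L_neutral = 10, L_outlier = 1, seed = 28)
  fr <- genotypes_to_frequencies(sim$genotypes)
  # knock out one locus in most populations
  fr$freq[[1]][1:8, ] <- NA
  fr$n[1:8, 1] <- NA
  ds <- afreq_dataset(fr$freq, fr$n, ploidy = fr$ploidy)
  expect_warning(sc <- scan_loci(ds, mds, top_k = 2), "excluded")
  expect_false(fr$loci[1] %in% sc$records$locus)
})

test_that("PCA of allele frequencies has coherent variance accounting", {
  set.seed(111)
  base <- runif(10)
  x <- cbind(l1 = base, l2 = 2 * base + 1)  # perfectly correlated pair
  rownames(x) <- paste0("P", 1:10)
  pc <- pca_allele_frequencies(x)
  expect_equal(pc$var_prop[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$var_prop), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(pc$scores))), 1e-12)
  # zero-variance columns are dropped with a warning
  x2 <- cbind(x, l3 = rep(0.5, 10))
  expect_warning(pca_allele_frequencies(x2), "zero-variance")
  expect_error(pca_allele_frequencies(x[, 1, drop = FALSE]), ">= 2")
})

test_that("leading PCs recover the planted latent axes", {
  ls <- simulate_structure(60, seed = 36)
  sim <- simulate_snp_dataset(ls, L_neutral = 40, L_outlier = 5, seed = 37)
  fr <- genotypes_to_frequencies(sim$genotypes)
  pc <- pca_allele_frequencies(focal_allele_matrix(fr))
  cors <- abs(cor(pc$scores[, 1:2], cbind(ls$a1, ls$a2)))
  # each truth axis is captured by one of the two leading PCs
  expect_gt(max(cors[, 1]), 0.8)
  expect_gt(max(cors[, 2]), 0.8)
})
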
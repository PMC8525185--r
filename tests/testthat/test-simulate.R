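test_that("latent structure construction is deterministic and well-formed", {
  ls <- simulate_structure(10, focal_fraction = 0.2, seed = 1)
  expect_equal(sum(ls$region == ls$focal_region), 2)
  expect_true(all(diff(ls$a1) > 0))
  expect_equal(mean(ls$a1), 0, tolerance = 1e-12)
  expect_equal(sd(ls$a1), 1, tolerance = 1e-12)
  expect_equal(mean(ls$a2), 0, tolerance = 1e-12)
  expect_equal(sd(ls$a2), 1, tolerance = 1e-12)
  expect_equal(cor(ls$a1, rank(ls$coast_pos)), 1)
  ls2 <- simulate_structure(10, focal_fraction = 0.2, seed = 1)
  expect_identical(ls, ls2)
  # coordinates stay in bounds, longitudes normalized
  expect_true(all(abs(ls$locations$latitude) <= 90))
  expect_true(all(ls$locations$longitude > -180 & ls$locations$longitude <= 180))
  expect_error(simulate_structure(8, focal_fraction = 0.45), "too small")
  expect_error(simulate_structure(5), ">= 8")
})

test_that("microsatellite generator hits the no-differentiation limit and is monotone", {
  ls <- simulate_structure(20, seed = 2)
  d0 <- simulate_msat_frequencies(ls, target_fst = 0, n_per_pop = 200, seed = 3)
  f0 <- pairwise_fst(d0)
  expect_lt(abs(mean(f0$fst[upper.tri(f0$fst)])), 0.003)
  # doubling the target strictly increases realized mean G_ST (5 seeds)
  for (s in 1:5) {
    lo <- simulate_msat_frequencies(ls, target_fst = 0.01,
                                    mean_he_target = 0.85, seed = 50 + s)
    hi <- simulate_msat_frequencies(ls, target_fst = 0.02,
                                    mean_he_target = 0.85, seed = 50 + s)
    mlo <- mean(pairwise_fst(lo)$fst[upper.tri(diag(20))])
    mhi <- mean(pairwise_fst(hi)$fst[upper.tri(diag(20))])
    expect_lt(mlo, mhi)
  }
  # determinism
  a <- simulate_msat_frequencies(ls, seed = 9)
  b <- simulate_msat_frequencies(ls, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_msat_frequencies(ls, mean_he_target = 0.95),
               "infeasible")
})

test_that("SNP generator plants the requested outliers and degenerates cleanly", {
  ls <- simulate_structure(20, seed = 4)
  sim <- simulate_snp_dataset(ls, L_neutral = 10, L_outlier = 5,
                              effect_scale = 3, seed = 5)
  expect_equal(sum(sim$truth$is_outlier), 5)
  expect_true(all(abs(sim$truth$b2[sim$truth$is_outlier]) >= 3))
  expect_true(all(abs(sim$truth$b2[sim$truth$is_outlier]) <= 6))
  # outlier |b2| separates from neutral |b2| by construction
  expect_gt(min(abs(sim$truth$b2[sim$truth$is_outlier])),
            max(abs(sim$truth$b2[!sim$truth$is_outlier])))
  expect_identical(sim,
                   simulate_snp_dataset(ls, L_neutral = 10, L_outlier = 5,
                                        effect_scale = 3, seed = 5))
  # zero-effect limit: frequencies flat, pairwise G_ST near zero
  nul <- simulate_snp_dataset(ls, L_neutral = 30, L_outlier = 0,
                              neutral_sd = 0, n_per_pop = 100, seed = 6)
  expect_true(all(nul$truth$b1 == 0) || all(abs(nul$truth$b1) < 1e-12))
  f <- pairwise_fst(genotypes_to_frequencies(nul$genotypes))
  expect_lt(abs(mean(f$fst[upper.tri(f$fst)])), 0.005)
})

test_that("focal-discovery ascertainment inflates discovery-region diversity", {
  wins <- 0L
  for (s in 1:3) {
    ls <- simulate_structure(40, seed = s)
    sim <- simulate_snp_dataset(ls, L_neutral = 30, L_outlier = 2,
                                ascertainment = "focal-discovery", seed = s + 10)
    he <- expected_heterozygosity(genotypes_to_frequencies(sim$genotypes))
    disc <- ls$region == "Western Alaska"
    if (mean(he$pop_mean[disc]) > mean(he$pop_mean[!disc])) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
  # infeasible ascertainment errors out rather than looping forever
  ls <- simulate_structure(20, seed = 1)
  expect_error(simulate_snp_dataset(ls, L_neutral = 10, L_outlier = 0,
                                    ascertainment = "focal-discovery",
                                    maf_min = 0.51, seed = 2),
               "infeasible")
})

test_that("mtDNA-like locus puts the major allele near its targets", {
  focal_means <- vapply(1:20, function(s) {
    ls <- simulate_structure(60, seed = s)
    d <- simulate_mtdna_locus(ls, seed = s + 300)
    mean(d$freq[[1]][ls$region == ls$focal_region, 2])
  }, 0)
  expect_lt(abs(mean(focal_means) - 0.21), 0.05)
  ls <- simulate_structure(20, seed = 1)
  d <- simulate_mtdna_locus(ls, seed = 2)
  expect_equal(d$ploidy[[1]], 1L)
  out <- d$freq[[1]][ls$region != ls$focal_region, 2]
  expect_true(all(abs(out - 0.98) < 1e-12))
  # biallelic haploid locus is valid
  d2 <- simulate_mtdna_locus(ls, n_alleles = 2, seed = 3)
  expect_equal(ncol(d2$freq[[1]]), 2)
  expect_s3_class(d2, "afreq_dataset")
  # empty focal region: uniform background locus
  ls0 <- ls
  ls0$region[ls0$region == ls0$focal_region] <- "Russia"
  d3 <- simulate_mtdna_locus(ls0, seed = 4)
  expect_true(all(abs(d3$freq[[1]][, 2] - 0.98) < 1e-12))
  expect_error(simulate_mtdna_locus(ls, focal_major_freq = 0.99,
                                    background_major_freq = 0.98),
               "focal_major_freq")
})
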
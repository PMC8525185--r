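test_that("expected heterozygosity matches closed-form values and bounds", {
  freq <- list(
    l1 = rbind(P1 = c(0.5, 0.5), P2 = c(1, 0)),
    l2 = rbind(P1 = rep(0.1, 10), P2 = c(0.9, 0.1, rep(0, 8))))
  for (l in names(freq)) colnames(freq[[l]]) <- paste0("a", seq_len(ncol(freq[[l]])))
  d <- expected_heterozygosity(quick_afreq(freq))
  expect_equal(unname(d$he["P1", "l1"]), 0.5)
  expect_equal(unname(d$he["P2", "l1"]), 0)
  expect_equal(unname(d$he["P1", "l2"]), 0.9)
  # property: bounds 0 <= He <= 1 - 1/A, equality only at equifrequency
  set.seed(61)
  for (i in 1:50) {
    A <- sample(2:20, 1)
    p <- {x <- rgamma(A, 0.5); x / sum(x)}
    he <- 1 - sum(p^2)
    expect_gte(he, 0)
    expect_lte(he, 1 - 1 / A)
  }
  # synthetic defaults land near the 0.89 calibration target
  ls <- simulate_structure(60, seed = 8)
  ds <- simulate_msat_frequencies(ls, seed = 88)
  expect_lt(abs(expected_heterozygosity(ds)$overall_mean - 0.89), 0.05)
})

test_that("regional summaries group populations correctly", {
  ls <- simulate_structure(20, seed = 2)
  ds <- simulate_msat_frequencies(ls, seed = 3)
  d <- expected_heterozygosity(ds)
  expect_setequal(d$region_stats$region, unique(ls$region))
  expect_equal(sum(d$region_stats$n_pops), 20)
})

test_that("spectrum binning follows the worked folded example", {
  freq <- list(l1 = rbind(P1 = c(0.9, 0.1)), l2 = rbind(P1 = c(0.6, 0.4)))
  for (l in names(freq)) colnames(freq[[l]]) <- c("a1", "a2")
  ds <- quick_afreq(freq)
  sp <- allele_frequency_spectrum(ds, region_map = c(P1 = "R"), bins = 5,
                                  folded = TRUE)
  expect_equal(unname(sp$counts["R", ]), c(1, 0, 0, 1, 0))
  expect_equal(sp$edges, seq(0, 0.5, by = 0.1))
  # folded mass never exceeds 0.5: top edge is 0.5 and every locus lands
  set.seed(13)
  gd <- random_genotype_dataset(J = 4, L = 6, n = 20, max_allele = 2,
                                missing = FALSE, seed = 13)
  ds2 <- genotypes_to_frequencies(gd)
  sp2 <- allele_frequency_spectrum(ds2, region_map = setNames(rep("R", 4), ds2$pops),
                                   bins = 8, folded = TRUE)
  expect_equal(sum(sp2$counts), sp2$locus_count[["R"]])
  expect_equal(max(sp2$edges), 0.5)
  # a region present only as an unused factor level yields an empty row
  rm <- factor(setNames(rep("R", 4), ds2$pops), levels = c("R", "Empty"))
  sp3 <- allele_frequency_spectrum(ds2, region_map = rm, bins = 4)
  expect_equal(unname(sp3$counts["Empty", ]), rep(0L, 4))
})

test_that("ascertainment empties the discovery region's rare-allele bin", {
  # a panel large and variable enough for per-bin counts to resolve the
  # regional contrast (small panels leave zero-count ties between regions)
  wins <- 0L
  for (s in 1:10) {
    ls <- simulate_structure(60, seed = s)
    sim <- simulate_snp_dataset(ls, L_neutral = 300, L_outlier = 2,
                                neutral_sd = 1,
                                ascertainment = "focal-discovery",
                                seed = s + 70)
    ds <- genotypes_to_frequencies(sim$genotypes)
    sp <- allele_frequency_spectrum(ds, bins = 10, folded = TRUE)
    low <- sp$counts[, 1]
    if (low["Western Alaska"] < min(low[rownames(sp$counts) != "Western Alaska"]))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("connectivity edges respect the strict threshold and clamping", {
  m <- rbind(c(0, 0.005, 0.02), c(0.005, 0, 0.009), c(0.02, 0.009, 0))
  g <- connectivity_edges(quick_fst(m), threshold = 0.01)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$pop_a, g$edges$pop_b),
                  c("P1 P2", "P2 P3"))
  expect_equal(g$edges$four_nem, 1 / g$edges$fst - 1)
  # threshold zero yields no edges even with negative estimates present
  m2 <- m; m2[1, 2] <- m2[2, 1] <- -0.003
  g0 <- connectivity_edges(quick_fst(m2), threshold = 0)
  expect_equal(nrow(g0$edges), 0)
  # clamped negative pair is an edge at positive thresholds, with Inf migrants
  g2 <- connectivity_edges(quick_fst(m2), threshold = 0.01)
  expect_true(is.infinite(g2$edges$four_nem[g2$edges$pop_b == "P2"]))
  # edge count is non-increasing as the threshold decreases
  thr <- c(0.05, 0.02, 0.01, 0.005, 0)
  counts <- vapply(thr, function(t) nrow(connectivity_edges(quick_fst(m), t)$edges), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("island-model conversion matches its closed form and inverts", {
  expect_identical(migrants_from_fst(0.01), 99)
  expect_equal(migrants_from_fst(0.5), 1)
  expect_equal(migrants_from_fst(1), 0)
  expect_error(migrants_from_fst(0), "undefined")
  expect_error(migrants_from_fst(-0.1), "undefined")
  expect_error(migrants_from_fst(1.2), "<= 1")
  fst <- runif(50, 1e-4, 1)
  expect_equal(1 / (migrants_from_fst(fst) + 1), fst, tolerance = 1e-12)
})

test_that("color gradient maps extremes to blue and red, affinely invariant", {
  col <- color_gradient(c(0.2, 0.5, 0.8))
  expect_equal(unname(col),
               unname(cbind(c(0, 0.5, 1), 0, c(1, 0.5, 0))))
  v <- runif(10)
  expect_equal(color_gradient(v), color_gradient(3 * v + 2))
  expect_error(color_gradient(rep(0.4, 5)), "all values equal")
  # orientation flip for completeness
  colb <- color_gradient(c(0, 1), orientation = "high_blue")
  expect_equal(unname(colb[1, ]), c(1, 0, 0))
})
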
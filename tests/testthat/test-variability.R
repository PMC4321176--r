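test_that("mean_normalize centers and probe_range matches brute force", {
  expect_equal(mean_normalize(c(0.2, 0.4, 0.6)), c(-0.2, 0, 0.2))
  expect_equal(mean_normalize(rep(0.3, 5)), rep(0, 5))
  set.seed(41)
  v <- runif(25)
  expect_lt(abs(sum(mean_normalize(v))), 1e-12)

  expect_equal(probe_range(c(0.1, 0.9)), 0.8)
  expect_equal(probe_range(rep(0.4, 6)), 0)
  expect_equal(probe_range(v),
               max(abs(outer(v, v, "-"))))  # exhaustive pairwise oracle
})

test_that("beta transform has closed-form anchors and exact inverses", {
  expect_equal(beta_transform(0.5), 0)
  expect_equal(beta_transform(0.8), 2)  # log2(4)
  expect_equal(beta_transform(0.5, "arcsine"), asin(sqrt(0.5)))
  set.seed(42)
  b <- runif(100, 0.001, 0.999)
  for (mode in c("logit", "arcsine")) {
    expect_lt(max(abs(beta_inverse_transform(beta_transform(b, mode),
                                             mode) - b)), 1e-12)
    # strictly monotone
    expect_true(all(diff(beta_transform(sort(b), mode)) > 0))
  }
  expect_error(beta_transform(c(0.2, 0)), "replace zeros|strictly inside")
  expect_error(beta_transform(1), "strictly inside")
})

test_that("levene_test reproduces a hand-worked case and the car oracle", {
  # identical groups and centering invariance
  g <- c(-1.2, 0.3, 0.9, 1.4)
  expect_equal(levene_test(g, g)[["stat"]], 0, tolerance = 1e-12)
  base <- levene_test(c(-1, 0, 1, 2), c(-4, 0, 4, 8))
  shifted <- levene_test(c(-1, 0, 1, 2) + 10, c(-4, 0, 4, 8) - 3)
  expect_equal(base, shifted)
  expect_equal(levene_test(rep(1, 3), rep(5, 3)), c(stat = 0, p = 1))

  # hand-worked Brown-Forsythe: |dev| from medians, one-way F
  # a = (-1,0,1): z = (1,0,1); b = (-10,0,10): z = (10,0,10)
  # SSB = 54, SSW = 202/3, W = 4*54/(202/3) = 324/101
  hw <- levene_test(c(-1, 0, 1), c(-10, 0, 10))
  expect_equal(hw[["stat"]], 324 / 101)
  expect_equal(hw[["p"]], pf(324 / 101, 1, 4, lower.tail = FALSE))

  skip_if_not_installed("car")
  set.seed(43)
  for (rep in 1:10) {
    a <- rnorm(25); b <- rnorm(25, sd = runif(1, 0.5, 2))
    for (ctr in c("median", "mean")) {
      ours <- levene_test(a, b, center = ctr)
      ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 25)),
                             center = ctr)
      expect_equal(ours[["stat"]], ref[1, "F value"])
      expect_equal(ours[["p"]], ref[1, "Pr(>F)"])
    }
  }
})

test_that("variance concordance band is closed and scale invariant", {
  expect_identical(variance_concordance(1.0, 1.1), "within_band")
  expect_identical(variance_concordance(1.0, 1.3), "outside_band")
  expect_identical(variance_concordance(1.0, 1.2), "within_band")  # boundary
  expect_identical(variance_concordance(1.0, 0.8), "within_band")  # boundary
  expect_warning(z <- variance_concordance(0, 1), "zero reference")
  expect_identical(z, "outside_band")
  set.seed(44)
  va <- runif(50, 0.1, 2); vb <- runif(50, 0.1, 2)
  for (c_mult in c(0.01, 3, 1000)) {
    expect_identical(variance_concordance(va * c_mult, vb * c_mult),
                     variance_concordance(va, vb))
  }
})

test_that("variable_loci uses a strict cutoff and is monotone", {
  sds <- c(cg1 = 0.05, cg2 = 0.15, cg3 = 0.35)
  expect_setequal(variable_loci(sds, 0.1), c("cg2", "cg3"))
  expect_setequal(variable_loci(sds, 0.3), "cg3")
  expect_identical(variable_loci(c(cg1 = 0.1), 0.1), character(0))  # strict
  set.seed(45)
  r <- setNames(runif(100, 0, 0.5), sprintf("cg%03d", 1:100))
  thresholds <- seq(0.05, 0.45, by = 0.05)
  counts <- vapply(thresholds, function(t) length(variable_loci(r, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cross-tissue probe correlation: anchors and null tail rate", {
  set.seed(46)
  a <- matrix(runif(3 * 25, 0.1, 0.9), 3, 25)
  b <- a
  b[2, ] <- 1 - a[2, ]
  ds <- make_matched(a, b)
  cc <- cross_tissue_probe_correlation(ds)
  expect_equal(cc$cross_r, c(1, -1, 1))

  # independent tissues: |r| > 0.5 rate matches the analytic null tail
  a <- matrix(runif(998 * 25), 998, 25)
  b <- matrix(runif(998 * 25), 998, 25)
  cc <- cross_tissue_probe_correlation(make_matched(a, b))
  t0 <- 0.5 * sqrt(23 / (1 - 0.25))
  p_tail <- 2 * pt(-t0, 23)                  # P(|r| > 0.5) under the null
  obs <- mean(abs(cc$cross_r) > 0.5)
  expect_lt(abs(obs - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / 998) + 1e-3)
  expect_lt(abs(mean(abs(cc$cross_r)) - sqrt(2 / (pi * 24))), 0.02)
})

test_that("variability table is internally consistent on synthetic data", {
  sim <- simulate_cohort(small_config(seed = 47))
  ds <- filter_probes(sim$data, qc_config())$data
  v <- variability(ds)
  expect_identical(attr(v, "transform"), "logit")
  expect_true(all(v$levene_p_bh >= v$levene_p))
  expect_true(all(v$range_a >= 0 & v$range_a <= 1))
  expect_true(all(v$sd_a >= 0))
  # concordance is a pure function of the ratio and the band
  within <- v$concordance == "within_band"
  expect_identical(within, v$variance_ratio >= 0.8 & v$variance_ratio <= 1.2)
  # swapping the tissues relabels the outputs
  swapped <- matched_dataset(ds$tissue_b, ds$tissue_a, ds$annotation,
                             ds$samples, ds$subject_order,
                             tissue_labels = c(a = ds$tissue_labels[["b"]],
                                               b = ds$tissue_labels[["a"]]))
  v2 <- variability(swapped)
  expect_equal(v2$var_t_a, v$var_t_b)
  expect_equal(v2$levene_stat, v$levene_stat)
  expect_equal(v2$cross_r, v$cross_r)
})
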
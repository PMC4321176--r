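test_that("paired t-test matches the reference implementation and contracts", {
  set.seed(21)
  x <- runif(25, 0.1, 0.9)
  y <- pmin(pmax(x + rnorm(25, 0.05, 0.1), 0), 1)
  got <- paired_ttest(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(unname(got["t_stat"]), unname(ref$statistic))
  expect_equal(unname(got["p_raw"]), ref$p.value)

  # invariance under a common shift of every pair
  shifted <- paired_ttest(x + 0.42, y + 0.42)
  expect_equal(got, shifted)

  # degenerate contracts
  expect_equal(paired_ttest(x, x), c(t_stat = 0, p_raw = 1))
  const <- paired_ttest(rep(0.2, 4), rep(0.3, 4))
  expect_identical(unname(const["t_stat"]), Inf)
  expect_identical(unname(const["p_raw"]), .Machine$double.xmin)
  expect_error(paired_ttest(c(0.1, 0.2), c(0.2, 0.3)), "at least 3")
})

test_that("bh_adjust reproduces hand-computed values and the step-up oracle", {
  expect_equal(bh_adjust(c(0.005, 0.5, 1.0)), c(0.015, 0.75, 1.0))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  step_up_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, p[o[i]] * m / i)
      q[o[i]] <- min(1, prev)
    }
    q
  }
  set.seed(22)
  for (rep in 1:20) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up_oracle(p))
    expect_true(all(adj >= p))
    expect_true(!is.unsorted(adj[order(p)]))
  }
})

test_that("specificity classes follow the p and delta-beta thresholds", {
  expect_identical(classify_specificity(0.0005, 0.45), "highly_tissue_specific")
  expect_identical(classify_specificity(0.0005, 0.25), "tissue_specific")
  expect_identical(classify_specificity(0.0005, -0.45), "highly_tissue_specific")
  expect_identical(classify_specificity(0.01, 0.9), "none")
  expect_identical(classify_specificity(0.0005, 0.2), "none")  # strict >

  # monotone in the delta cutoff: lowering it never loses calls
  set.seed(23)
  p <- runif(200, 0, 0.002)
  d <- runif(200, -0.6, 0.6)
  n_at <- function(cut) sum(classify_specificity(p, d,
                                                 delta_specific = cut) != "none")
  cuts <- seq(0.5, 0.05, by = -0.05)
  expect_true(!is.unsorted(vapply(cuts, n_at, numeric(1))))
})

test_that("methylation categories use <20%, closed 20-80%, >80%", {
  expect_identical(methylation_category(c(0.10, 0.50, 0.90)),
                   c("hypomethylated", "heterogeneous", "hypermethylated"))
  expect_identical(methylation_category(c(0.20, 0.80)),
                   c("heterogeneous", "heterogeneous"))
  expect_error(methylation_category(1.2), "\\[0, 1\\]")
})

test_that("one-way ICC equals an explicit ANOVA-table oracle", {
  # degenerate anchors
  expect_equal(icc_oneway(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  expect_equal(icc_oneway(c(0.2, 0.2), c(0.8, 0.8)), -1)
  expect_true(is.na(icc_oneway(rep(0.5, 4), rep(0.5, 4))))

  aov_oracle <- function(a, b) {
    df <- data.frame(value = c(a, b),
                     subject = factor(rep(seq_along(a), 2)))
    tab <- summary(stats::aov(value ~ subject, data = df))[[1]]
    msb <- tab["subject", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    (msb - msw) / (msb + msw)
  }
  set.seed(24)
  for (rep in 1:10) {
    a <- runif(25)
    b <- pmin(pmax(a + rnorm(25, 0, 0.2) + rnorm(1, 0, 0.3), 0), 1)
    icc <- icc_oneway(a, b)
    expect_equal(icc, aov_oracle(a, b))
    expect_gte(icc, -1); expect_lte(icc, 1)
    # symmetric in tissue labels
    expect_equal(icc_oneway(b, a), icc)
  }
})

test_that("sample-wise correlations match hand computation and pairing", {
  A <- matrix(c(0.1, 0.4, 0.9,
                0.2, 0.5, 0.7), 3, 2,
              dimnames = list(paste0("cg", 1:3), c("a1", "a2")))
  B <- A + 0.01
  colnames(B) <- c("b1", "b2")
  ds <- make_matched(A, B)
  cs <- samplewise_correlations(ds)
  expect_length(cs$within_a, 1)                    # C(2,2) pairs
  expect_equal(cs$within_a, cor(A[, 1], A[, 2]))
  expect_length(cs$between, 2)                     # matched mode
  expect_equal(cs$between, c(1, 1))                # B is a shifted copy of A
  all_pairs <- samplewise_correlations(ds, between_mode = "all_pairs")
  expect_length(all_pairs$between, 4)

  # planted LC tissue divergence pushes LC below HC (generator structure)
  sim <- simulate_cohort(small_config(seed = 31, n_probes = 400))
  run_ds <- filter_probes(sim$data, qc_config())$data
  cs2 <- samplewise_correlations(run_ds)
  expect_lt(cs2$between_by_class[["LC"]], cs2$between_by_class[["HC"]])
})

test_that("global paired tissue test has the exact signed-rank tail", {
  set.seed(25)
  a <- matrix(runif(40 * 25, 0.2, 0.6), 40, 25)
  # every subject mean strictly larger in tissue B, all shifts distinct
  # (tied |differences| would force the normal approximation)
  b <- pmin(a + rep(runif(25, 0.02, 0.1), each = 40), 1)
  ds <- make_matched(a, b)
  gt <- global_tissue_test(ds)
  expect_identical(gt$n_b_greater, 25L)
  expect_equal(gt$p, 2 / 2^25)  # complete one-sided ranking, two-tailed

  ident <- make_matched(a, a)
  expect_message(gt0 <- global_tissue_test(ident), "undefined")
  expect_true(is.na(gt0$p))
})

test_that("a planted global offset is detected in almost every cohort", {
  hits <- 0
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(small_config(seed = 3000 + s, n_probes = 120,
                                        global_offset = 0.05))
    ds <- sim$data
    p <- global_tissue_test(ds)$p
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_seeds, 0.95)
})
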
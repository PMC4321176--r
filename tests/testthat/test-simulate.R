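test_that("the generator is deterministic and respects value bounds", {
  s1 <- simulate_cohort(small_config(seed = 71))
  s2 <- simulate_cohort(small_config(seed = 71))
  expect_identical(s1$data$tissue_a$beta, s2$data$tissue_a$beta)
  expect_identical(s1$data$tissue_b$beta, s2$data$tissue_b$beta)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(small_config(seed = 72))
  expect_false(identical(s1$data$tissue_a$beta, s3$data$tissue_a$beta))

  expect_true(all(s1$data$tissue_a$beta >= 0 & s1$data$tissue_a$beta <= 1))
  expect_true(all(s1$data$tissue_b$beta >= 0 & s1$data$tissue_b$beta <= 1))
})

test_that("injected artifacts carry their signatures and QC recovers them", {
  cfg <- small_config(seed = 73)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth

  zh <- truth$probe_id[truth$qc_artifact == "zero_heavy"]
  expect_true(all(rowSums(sim$data$tissue_a$beta[zh, , drop = FALSE] == 0)
                  == cfg$n_subjects - 1))
  # scattered exact zeros exist outside the zero-heavy probes too
  clean <- truth$probe_id[truth$qc_artifact == "none"]
  expect_gt(sum(sim$data$tissue_a$beta[clean, ] == 0), 0)

  out <- filter_probes(sim$data, qc_config())
  expect_identical(out$report$n_retained, cfg$n_probes)
  expect_setequal(out$report$removed$sex_chromosome,
                  truth$probe_id[truth$qc_artifact == "x_chromosome"])
  expect_setequal(out$report$removed$snp_overlap,
                  truth$probe_id[truth$qc_artifact == "snp"])
  expect_setequal(out$report$removed$zero_beta, zh)
  expect_setequal(out$report$removed$detection_failure,
                  truth$probe_id[truth$qc_artifact == "detection_failure"])
})

test_that("a null configuration yields almost no tissue-specific calls", {
  rates <- vapply(1:20, function(s) {
    sim <- simulate_cohort(small_config(seed = 700 + s,
                                        frac_tissue_specific = 0,
                                        global_offset = 0))
    ds <- filter_probes(sim$data, qc_config())$data
    spec <- tissue_specificity(ds)
    mean(spec$spec_class != "none")
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})

test_that("planted structure: LC bias, delta-beta range, variance ratios", {
  cfg <- simulation_config(seed = 74)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth[sim$truth$qc_artifact == "none", ]

  ts <- truth[truth$is_tissue_specific, ]
  expect_equal(nrow(ts), round(cfg$frac_tissue_specific * cfg$n_probes))
  expect_true(all(abs(ts$true_delta_beta) >= cfg$delta_beta_range[1] - 1e-9))
  expect_true(all(abs(ts$true_delta_beta) <= cfg$delta_beta_range[2] + 1e-9))
  # LC oversampling: LC rate among tissue-specific probes exceeds base rate
  expect_gt(mean(ts$cpg_class == "LC"), mean(truth$cpg_class == "LC"))
  # and class-level mean |delta beta| is larger for LC than HC
  mean_abs_delta <- tapply(abs(truth$true_delta_beta), truth$cpg_class, mean)
  expect_gt(mean_abs_delta[["LC"]], mean_abs_delta[["HC"]])

  vd <- truth[truth$is_variance_discordant, ]
  expect_true(all(vd$true_variance_ratio %in% cfg$variance_ratios))
  expect_false(any(is.na(truth$true_delta_beta)))

  # planted association probes are disjoint from tissue-specific ones
  assoc <- truth[!is.na(truth$associated_variable), ]
  expect_identical(nrow(assoc), 50L)
  expect_false(any(assoc$is_tissue_specific))
})

test_that("truth recovery report scores perfect and chance predictions", {
  sim <- simulate_cohort(small_config(seed = 75))
  truth <- sim$truth[sim$truth$qc_artifact == "none", ]
  perfect <- data.frame(
    probe_id = truth$probe_id,
    spec_class = ifelse(truth$is_tissue_specific, "tissue_specific", "none"),
    stringsAsFactors = FALSE)
  rep1 <- truth_recovery_report(truth, spec_results = perfect)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$fdr, 0)

  set.seed(76)
  frac <- 0.3
  random <- perfect
  random$spec_class <- ifelse(runif(nrow(random)) < frac,
                              "tissue_specific", "none")
  rep2 <- truth_recovery_report(truth, spec_results = random)
  expect_lt(abs(rep2$sensitivity - frac), 0.15)  # chance level

  bad <- perfect
  bad$probe_id[1] <- "cg_not_in_truth"
  expect_error(truth_recovery_report(truth, spec_results = bad), "universe")
})

test_that("infeasible planted counts are rejected", {
  expect_error(simulation_config(n_probes = 100, frac_tissue_specific = 0.9,
                                 planted_assoc = list(
                                   sex = list(n_probes = 50, effect = 0.15))),
               "exceed")
})
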
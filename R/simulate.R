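#' Configuration for the synthetic matched-cohort generator
#'
#' Defaults emulate a 25-subject matched two-tissue cohort measured on a
#' promoter CpG panel of 998 analyzable probes: a bimodal beta
#' landscape dominated by hypo- and hypermethylated sites, CpG density
#' classes at roughly 21% LC / 14% IC / 50% HC / 15% uncategorized,
#' about 18% tissue-specific probes with |delta beta| between 0.2 and
#' 0.6 concentrated (2x) in LC regions, 15% variance-discordant probes
#' at a 3-fold variance ratio, a small (+0.02) global tissue offset,
#' 50 sex-associated probes at delta beta 0.15, and a handful of
#' QC-artifact probes (SNP-flagged, sex-chromosome, polymorphic,
#' zero-heavy, detection-failing) injected on top so the filters have
#' work to do.
#'
#' @param n_subjects Number of matched subjects.
#' @param n_probes Number of clean (QC-passing) probes.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-identically.
#' @param class_proportions Named proportions over
#'   `c("LC", "IC", "HC", "uncategorized")`; must sum to 1.
#' @param frac_tissue_specific Fraction of clean probes with a planted
#'   tissue effect.
#' @param delta_beta_range Range of planted |delta beta| on the beta
#'   scale.
#' @param lc_specificity_bias Sampling-weight multiplier concentrating
#'   tissue-specific probes in LC regions.
#' @param frac_variance_discordant Fraction of clean probes whose
#'   tissue-B noise variance is scaled by a ratio drawn from
#'   `variance_ratios`.
#' @param variance_ratios Candidate tissue-B/tissue-A variance ratios.
#' @param global_offset Mean tissue-B minus tissue-A shift (beta scale)
#'   applied to probes without a planted tissue effect.
#' @param planted_assoc Named list per demographic variable, each a list
#'   with `n_probes`, `effect` (delta beta across groups or per
#'   covariate span) and optionally `tissue` (`"a"`/`"b"`, default
#'   `"b"`).
#' @param noise_sd Residual SD on the transformed (base-2 logit) scale.
#' @param noise_sd_spread Log-normal spread of per-probe noise SDs
#'   (sdlog; 0 gives identical SDs).
#' @param subject_sd SD of the global per-subject shift (transformed
#'   scale), shared across probes and tissues.
#' @param tissue_noise_scale Named multipliers `c(a = ..., b = ...)` on
#'   the noise SD per tissue; the default makes tissue A the more
#'   variable one.
#' @param qc_artifacts Named integer counts of injected artifact probes:
#'   `snp`, `x_chromosome`, `polymorphic`, `zero_heavy`,
#'   `detection_failure`.
#' @param n_scatter_zeros Exact-zero cells scattered into clean
#'   hypomethylated probes per tissue (exercises [replace_zeros()]).
#' @param tissue_labels Names of the two tissues in the sample sheet.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 25L,
                              n_probes = 998L,
                              seed = 1L,
                              class_proportions = c(LC = 0.21, IC = 0.14,
                                                    HC = 0.50,
                                                    uncategorized = 0.15),
                              frac_tissue_specific = 0.18,
                              delta_beta_range = c(0.2, 0.6),
                              lc_specificity_bias = 2,
                              frac_variance_discordant = 0.15,
                              variance_ratios = c(1 / 3, 3),
                              global_offset = 0.02,
                              planted_assoc = list(
                                sex = list(n_probes = 50L, effect = 0.15,
                                           tissue = "b")),
                              noise_sd = 0.35,
                              noise_sd_spread = 0.30,
                              subject_sd = 0.10,
                              tissue_noise_scale = c(a = 1.10, b = 0.90),
                              qc_artifacts = c(snp = 20L, x_chromosome = 15L,
                                               polymorphic = 8L,
                                               zero_heavy = 5L,
                                               detection_failure = 10L),
                              n_scatter_zeros = 8L,
                              tissue_labels = c(a = "BEC", b = "PBMC")) {
  stopifnot(n_subjects >= 4, n_probes >= 10)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("`class_proportions` must sum to 1", call. = FALSE)
  if (!setequal(names(class_proportions), CPG_CLASSES))
    stop("`class_proportions` must be named over ",
         paste(CPG_CLASSES, collapse = ", "), call. = FALSE)
  for (f in c(frac_tissue_specific, frac_variance_discordant))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  n_ts <- round(frac_tissue_specific * n_probes)
  n_assoc <- sum(vapply(planted_assoc, function(x) as.integer(x$n_probes),
                        integer(1)))
  if (n_ts + n_assoc > n_probes)
    stop("planted tissue-specific + association probes exceed `n_probes`",
         call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

logit2 <- function(b) log2(b / (1 - b))
invlogit2 <- function(m) 2^m / (1 + 2^m)

# Baseline mean beta on the transformed scale: a bimodal mixture
# concentrated near beta = 0.1 and 0.9 with a minority mid-range
# component, reproducing the hypo/hyper-dominated landscape of
# promoter CpG panels.
draw_baseline_m <- function(n) {
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.63, 0.26, 0.11))
  m <- numeric(n)
  m[comp == 1] <- stats::rnorm(sum(comp == 1), logit2(0.08), 0.7)
  m[comp == 2] <- stats::rnorm(sum(comp == 2), logit2(0.92), 0.7)
  m[comp == 3] <- stats::rnorm(sum(comp == 3), 0, 1.1)
  m
}

# Signed beta-scale shift from mean `m`, magnitude `d`, direction chosen
# at random among those keeping the target inside (0.03, 0.97); when the
# requested magnitude does not fit, it is clamped to the larger room.
plant_shift <- function(m, d, lo = 0.03, hi = 0.97) {
  room_up <- hi - m
  room_dn <- m - lo
  up_ok <- d <= room_up
  dn_ok <- d <= room_dn
  if (up_ok && dn_ok) sgn <- sample(c(-1, 1), 1)
  else if (up_ok) sgn <- 1
  else if (dn_ok) sgn <- -1
  else {
    sgn <- if (room_up >= room_dn) 1 else -1
    d <- max(room_up, room_dn)
  }
  sgn * d
}

#' Generate a synthetic matched two-tissue methylation cohort
#'
#' Simulates subject beta values on the base-2 logit scale as
#' `baseline + subject shift + tissue effect + demographic effect +
#' noise`, inverse-transforms to (0, 1), and injects QC-artifact probes
#' and scattered exact zeros. Planted tissue-specific, variance-
#' discordant and demographic effects are recorded in a per-probe truth
#' table so downstream calls can be scored by parameter recovery.
#'
#' @param config A [simulation_config()].
#' @return A list with `data` (a [matched_dataset()] including artifact
#'   probes, annotation, sample sheet and detection p-values) and
#'   `truth` (data frame, one row per probe).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  np <- config$n_probes
  art <- config$qc_artifacts
  n_art <- sum(art)
  n_all <- np + n_art

  probe_id <- sprintf("cg%05d", seq_len(n_all))
  artifact <- rep("none", n_all)
  if (n_art > 0) {
    slots <- sample(n_all, n_art)
    artifact[slots] <- rep(names(art), times = art)
  }
  clean <- artifact == "none"

  cls <- sample(names(config$class_proportions), n_all, replace = TRUE,
                prob = config$class_proportions)

  base_m <- draw_baseline_m(n_all)
  base_beta <- invlogit2(base_m)

  # planted effect assignment (clean probes only); tissue-specific
  # probes oversample LC regions, association probes are disjoint
  n_ts <- round(config$frac_tissue_specific * np)
  w <- ifelse(cls == "LC", config$lc_specificity_bias, 1) * clean
  ts_idx <- sample(n_all, n_ts, prob = w)
  is_ts <- seq_len(n_all) %in% ts_idx

  assoc_var <- rep(NA_character_, n_all)
  assoc_effect <- rep(NA_real_, n_all)
  pool <- which(clean & !is_ts)
  for (v in names(config$planted_assoc)) {
    spec_v <- config$planted_assoc[[v]]
    pick <- sample(pool, as.integer(spec_v$n_probes))
    assoc_var[pick] <- v
    pool <- setdiff(pool, pick)
  }

  n_vd <- round(config$frac_variance_discordant * np)
  vd_idx <- sample(which(clean), n_vd)
  var_ratio <- rep(1, n_all)
  var_ratio[vd_idx] <- sample(config$variance_ratios, n_vd, replace = TRUE)

  # tissue effect on the transformed scale, parameterized as a target
  # beta-scale shift of the mean; the shifted member of the pair is
  # chosen at random so neither tissue is systematically the divergent
  # one (a shift off the beta extremes inflates beta-scale spread, so a
  # fixed choice would bias the marginal SD distributions)
  true_delta <- numeric(n_all)
  delta_m_a <- numeric(n_all)
  delta_m_b <- numeric(n_all)
  for (i in which(is_ts)) {
    d <- stats::runif(1, config$delta_beta_range[1], config$delta_beta_range[2])
    shift <- plant_shift(base_beta[i], d)
    shift_m <- logit2(base_beta[i] + shift) - base_m[i]
    if (stats::runif(1) < 0.5) {
      delta_m_b[i] <- shift_m
      true_delta[i] <- shift
    } else {
      delta_m_a[i] <- shift_m
      true_delta[i] <- -shift
    }
  }
  # the global tissue offset is additive on the beta scale (a pure
  # location shift that leaves each probe's spread untouched); it is
  # applied to non-tissue-specific probes after inverse transformation
  off <- config$global_offset
  true_delta[!is_ts] <- off

  # demographics
  subj <- sprintf("S%02d", seq_len(n))
  sex <- sample(rep(c("male", "female"), times = c(15, 10))[seq_len(max(n, 2))][seq_len(n)])
  ethnicity <- sample(rep(c("caucasian", "non_caucasian"),
                          times = ceiling(c(18, 7) / 25 * n)))[seq_len(n)]
  age <- stats::runif(n, 26, 45)
  bmi <- pmin(pmax(stats::rlnorm(n, log(26), 0.20), 18.2), 47.9)
  alcohol <- stats::rpois(n, 3)
  covariates <- list(sex = sex, ethnicity = ethnicity, age = age,
                     bmi = bmi, alcohol = alcohol)

  # demographic effects on the transformed scale
  demo_m <- matrix(0, n_all, n)  # applied in the configured tissue only
  demo_tissue <- rep("b", n_all)
  for (i in which(!is.na(assoc_var))) {
    v <- assoc_var[i]
    spec_v <- config$planted_assoc[[v]]
    demo_tissue[i] <- if (is.null(spec_v$tissue)) "b" else spec_v$tissue
    vals <- covariates[[v]]
    d <- plant_shift(base_beta[i], spec_v$effect)
    assoc_effect[i] <- d
    shift_m <- logit2(base_beta[i] + d) - base_m[i]
    if (is.numeric(vals)) {
      demo_m[i, ] <- shift_m * (vals - min(vals)) / (max(vals) - min(vals))
    } else {
      lev <- sort(unique(vals))
      demo_m[i, vals == lev[2]] <- shift_m
    }
  }

  sigma <- config$noise_sd * exp(stats::rnorm(n_all, 0, config$noise_sd_spread))
  subj_shift <- stats::rnorm(n, 0, config$subject_sd)
  scale_a <- config$tissue_noise_scale[["a"]]
  scale_b <- config$tissue_noise_scale[["b"]]

  # the planted tissue-B/tissue-A variance ratio is split symmetrically
  # across the two tissues so discordant probes do not bias either
  # tissue's marginal SD distribution; discordant probes are exempt
  # from the global tissue scale so their realized ratio is exactly the
  # planted one
  disc <- var_ratio != 1
  sd_mult_a <- ifelse(disc, var_ratio^(-1 / 4), scale_a)
  sd_mult_b <- ifelse(disc, var_ratio^(1 / 4), scale_b)
  noise_a <- matrix(stats::rnorm(n_all * n), n_all, n) * (sigma * sd_mult_a)
  noise_b <- matrix(stats::rnorm(n_all * n), n_all, n) * (sigma * sd_mult_b)
  M_a <- base_m + delta_m_a + outer(rep(1, n_all), subj_shift) + noise_a
  M_b <- base_m + delta_m_b + outer(rep(1, n_all), subj_shift) + noise_b
  M_b <- M_b + demo_m * (demo_tissue == "b")
  M_a <- M_a + demo_m * (demo_tissue == "a")

  eps <- 1e-6
  beta_a <- pmin(pmax(invlogit2(M_a), eps), 1 - eps)
  beta_b <- invlogit2(M_b)
  beta_b[!is_ts, ] <- beta_b[!is_ts, ] + off
  beta_b <- pmin(pmax(beta_b, eps), 1 - eps)

  # QC artifacts and scattered zeros
  zh <- which(artifact == "zero_heavy")
  for (i in zh) {
    zero_cols <- sample(n, n - 1)
    beta_a[i, zero_cols] <- 0
    beta_a[i, setdiff(seq_len(n), zero_cols)] <- stats::runif(1, 0.01, 0.05)
  }
  hypo <- which(clean & base_beta < 0.2)
  for (tissue in c("a", "b")) {
    cells <- cbind(sample(hypo, config$n_scatter_zeros, replace = TRUE),
                   sample(n, config$n_scatter_zeros, replace = TRUE))
    if (tissue == "a") beta_a[cells] <- 0 else beta_b[cells] <- 0
  }

  det_a <- matrix(stats::runif(n_all * n, 0, 0.01), n_all, n)
  det_b <- matrix(stats::runif(n_all * n, 0, 0.01), n_all, n)
  for (i in which(artifact == "detection_failure")) {
    bad <- sample(n, 5)
    det_a[i, bad] <- stats::runif(5, 0.1, 0.9)
  }

  sample_a <- paste0(subj, "_", config$tissue_labels[["a"]])
  sample_b <- paste0(subj, "_", config$tissue_labels[["b"]])
  dimnames(beta_a) <- list(probe_id, sample_a)
  dimnames(beta_b) <- list(probe_id, sample_b)
  dimnames(det_a) <- dimnames(beta_a)
  dimnames(det_b) <- dimnames(beta_b)

  chromosome <- sample(paste0("chr", 1:22), n_all, replace = TRUE)
  chromosome[artifact == "x_chromosome"] <- "chrX"
  annotation <- data.frame(
    probe_id = probe_id,
    chromosome = chromosome,
    gene_symbol = sprintf("GENE%04d", sample(seq_len(ceiling(n_all / 2)),
                                             n_all, replace = TRUE)),
    cpg_class = cls,
    snp_overlap = artifact == "snp",
    polymorphic_cpg = artifact == "polymorphic",
    stringsAsFactors = FALSE)

  samples <- data.frame(
    sample_id = c(sample_a, sample_b),
    subject_id = rep(subj, 2),
    tissue = rep(unname(config$tissue_labels[c("a", "b")]), each = n),
    age = rep(age, 2), sex = rep(sex, 2), ethnicity = rep(ethnicity, 2),
    bmi = rep(bmi, 2), alcohol = rep(alcohol, 2),
    stringsAsFactors = FALSE)

  data <- matched_dataset(
    tissue_a = beta_matrix(beta_a, det_a),
    tissue_b = beta_matrix(beta_b, det_b),
    annotation = annotation, samples = samples,
    subject_order = subj,
    tissue_labels = config$tissue_labels)

  truth <- data.frame(
    probe_id = probe_id,
    cpg_class = cls,
    qc_artifact = artifact,
    baseline_mean_beta = base_beta,
    is_tissue_specific = is_ts,
    true_delta_beta = true_delta,
    is_variance_discordant = var_ratio != 1,
    true_variance_ratio = var_ratio,
    associated_variable = assoc_var,
    true_effect = assoc_effect,
    stringsAsFactors = FALSE)

  list(data = data, truth = truth)
}

#' Score pipeline calls against the planted truth
#'
#' Computes sensitivity, specificity and the observed false-discovery
#' proportion for each planted effect class, comparing pipeline outputs
#' with the generator's truth table over the QC-clean probe universe.
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param spec_results Optional [tissue_specificity()] table; calls are
#'   `spec_class != "none"`.
#' @param variability_results Optional [variability()] table; calls are
#'   `levene_p_bh < 0.05`.
#' @param assoc Optional [association_scan()] result; calls are the
#'   `significant` column, scored per planted variable.
#' @return Data frame with one row per scored effect class: `effect`,
#'   `n_true`, `n_called`, `tp`, `sensitivity`, `specificity`, `fdr`.
#' @export
truth_recovery_report <- function(truth, spec_results = NULL,
                                  variability_results = NULL, assoc = NULL) {
  score <- function(effect, called_ids, true_ids, universe) {
    if (length(setdiff(universe, truth$probe_id)) > 0)
      stop("result probes outside the truth universe", call. = FALSE)
    tp <- length(intersect(called_ids, true_ids))
    neg <- setdiff(universe, true_ids)
    data.frame(effect = effect,
               n_true = length(true_ids),
               n_called = length(called_ids),
               tp = tp,
               sensitivity = if (length(true_ids) > 0)
                 tp / length(true_ids) else NA_real_,
               specificity = if (length(neg) > 0)
                 1 - length(setdiff(called_ids, true_ids)) / length(neg)
               else NA_real_,
               fdr = if (length(called_ids) > 0)
                 length(setdiff(called_ids, true_ids)) / length(called_ids)
               else 0,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (!is.null(spec_results)) {
    universe <- spec_results$probe_id
    rows$ts <- score(
      "tissue_specific",
      spec_results$probe_id[spec_results$spec_class != "none"],
      truth$probe_id[truth$is_tissue_specific &
                     truth$probe_id %in% universe],
      universe)
  }
  if (!is.null(variability_results)) {
    universe <- variability_results$probe_id
    rows$vd <- score(
      "variance_discordant",
      variability_results$probe_id[
        !is.na(variability_results$levene_p_bh) &
        variability_results$levene_p_bh < 0.05],
      truth$probe_id[truth$is_variance_discordant &
                     truth$probe_id %in% universe],
      universe)
  }
  if (!is.null(assoc)) {
    for (v in unique(stats::na.omit(truth$associated_variable))) {
      res_v <- assoc$results[assoc$results$variable == v, , drop = FALSE]
      if (nrow(res_v) == 0) next
      universe <- res_v$probe_id
      rows[[paste0("assoc_", v)]] <- score(
        paste0("assoc_", v),
        res_v$probe_id[res_v$significant],
        truth$probe_id[!is.na(truth$associated_variable) &
                       truth$associated_variable == v &
                       truth$probe_id %in% universe],
        universe)
    }
  }
  if (length(rows) == 0)
    stop("no pipeline outputs supplied to score", call. = FALSE)
  do.call(rbind, c(rows, make.row.names = FALSE))
}
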
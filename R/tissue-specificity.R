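#' Probe-wise paired t-test between matched tissues
#'
#' One-sample t-test on the per-subject differences `d = y - x`:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom,
#' two-tailed. The matched design makes an equal-variance assumption
#' unnecessary. Degenerate cases follow a fixed contract: all
#' differences zero gives `t = 0, p = 1`; constant nonzero differences
#' give an infinite statistic with the smallest representable p-value.
#'
#' @param x,y Numeric vectors of per-subject beta values for one probe in
#'   tissue A (`x`) and the matched tissue B (`y`), same subject order.
#' @return Named numeric vector `c(t_stat, p_raw)`.
#' @examples
#' paired_ttest(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.7))
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length (matched subjects)", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("paired t-test needs at least 3 subjects", call. = FALSE)
  d <- y - x
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(c(t_stat = 0, p_raw = 1))
    return(c(t_stat = sign(m) * Inf, p_raw = .Machine$double.xmin))
  }
  t <- m / (s / sqrt(n))
  c(t_stat = t, p_raw = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order (monotone step-up FDR).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Classify tissue specificity of a probe
#'
#' A probe is tissue specific when its adjusted p-value is below
#' `p_threshold` and |delta beta| exceeds `delta_specific`; highly
#' tissue specific when |delta beta| additionally exceeds `delta_high`.
#'
#' @param p_bh Adjusted p-value(s).
#' @param delta_beta Signed mean beta difference(s) between tissues.
#' @param p_threshold Significance cutoff (default 0.001).
#' @param delta_specific,delta_high |delta beta| cutoffs (defaults 0.2, 0.4).
#' @return Character vector in
#'   `c("none", "tissue_specific", "highly_tissue_specific")`.
#' @export
classify_specificity <- function(p_bh, delta_beta, p_threshold = 0.001,
                                 delta_specific = 0.2, delta_high = 0.4) {
  n <- max(length(p_bh), length(delta_beta))
  p_bh <- rep_len(p_bh, n)
  delta_beta <- rep_len(delta_beta, n)
  out <- rep_len("none", n)
  sig <- !is.na(p_bh) & !is.na(delta_beta) & p_bh < p_threshold
  out[sig & abs(delta_beta) > delta_specific] <- "tissue_specific"
  out[sig & abs(delta_beta) > delta_high] <- "highly_tissue_specific"
  out
}

#' Methylation category of a mean beta value
#'
#' Standard categorisation of promoter CpG methylation: hypomethylated
#' below 20%, heterogeneously methylated in the closed interval
#' 20--80%, hypermethylated above 80%.
#'
#' @param mean_beta Mean beta value(s) in \[0, 1\].
#' @return Character vector in
#'   `c("hypomethylated", "heterogeneous", "hypermethylated")`.
#' @export
methylation_category <- function(mean_beta) {
  if (any(mean_beta < 0 | mean_beta > 1, na.rm = TRUE))
    stop("mean beta values must lie in [0, 1]", call. = FALSE)
  out <- rep_len("heterogeneous", length(mean_beta))
  out[mean_beta < 0.20] <- "hypomethylated"
  out[mean_beta > 0.80] <- "hypermethylated"
  out[is.na(mean_beta)] <- NA_character_
  out
}

#' One-way intraclass correlation for two matched measurements
#'
#' One-way random-effects consistency ICC with subject as the grouping
#' factor and k = 2 measurements (one per tissue):
#' `ICC = (MS_between - MS_within) / (MS_between + MS_within)`,
#' where `MS_between` is the between-subject mean square (inter-
#' individual spread) and `MS_within` the within-subject mean square
#' (the per-subject between-tissue difference). For k = 2 the value
#' lies in \[-1, 1\]: ICC near -1 means the between-tissue difference
#' dominates the between-subject difference; near +1 the reverse.
#'
#' @param a,b Numeric vectors of the two measurements per subject, same
#'   subject order.
#' @return The ICC, or `NA` when total variance is zero.
#' @examples
#' icc_oneway(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))  #  1
#' icc_oneway(c(0.2, 0.2), c(0.8, 0.8))            # -1
#' @export
icc_oneway <- function(a, b) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("ICC needs at least 2 subjects", call. = FALSE)
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  subject_means <- (a + b) / 2
  grand <- mean(subject_means)
  ss_between <- 2 * sum((subject_means - grand)^2)
  ss_within <- sum((a - subject_means)^2 + (b - subject_means)^2)
  ms_between <- ss_between / (n - 1)
  ms_within <- ss_within / n
  denom <- ms_between + ms_within
  if (denom == 0) return(NA_real_)
  (ms_between - ms_within) / denom
}

#' Probe-wise tissue-specificity table
#'
#' Runs the paired t-test on every probe, adjusts p-values by
#' Benjamini-Hochberg, computes per-tissue mean betas, the signed
#' delta beta (tissue B minus tissue A), the specificity class and the
#' one-way ICC.
#'
#' @param data A [matched_dataset()] (post QC).
#' @param p_threshold,delta_specific,delta_high Classification cutoffs,
#'   see [classify_specificity()].
#' @return Data frame with one row per probe: `probe_id`, `cpg_class`,
#'   `mean_beta_a`, `mean_beta_b`, `delta_beta`, `t_stat`, `p_raw`,
#'   `p_bh`, `spec_class`, `icc`.
#' @export
tissue_specificity <- function(data, p_threshold = 0.001,
                               delta_specific = 0.2, delta_high = 0.4) {
  stopifnot(inherits(data, "matched_dataset"))
  A <- data$tissue_a$beta
  B <- data$tissue_b$beta
  tt <- vapply(seq_len(nrow(A)),
               function(i) paired_ttest(A[i, ], B[i, ]),
               numeric(2))
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  delta <- mean_b - mean_a
  p_bh <- bh_adjust(tt["p_raw", ])
  icc <- vapply(seq_len(nrow(A)),
                function(i) icc_oneway(A[i, ], B[i, ]),
                numeric(1))
  data.frame(probe_id = rownames(A),
             cpg_class = data$annotation$cpg_class,
             mean_beta_a = unname(mean_a),
             mean_beta_b = unname(mean_b),
             delta_beta = unname(delta),
             t_stat = unname(tt["t_stat", ]),
             p_raw = unname(tt["p_raw", ]),
             p_bh = p_bh,
             spec_class = classify_specificity(p_bh, delta, p_threshold,
                                               delta_specific, delta_high),
             icc = icc,
             stringsAsFactors = FALSE)
}

#' Sample-wise Pearson correlation structure of a matched dataset
#'
#' Within-tissue: the Pearson correlation over probes for every
#' unordered pair of samples within a tissue (`n(n-1)/2` pairs).
#' Between-tissue: by default each subject's tissue-A profile against
#' the same subject's tissue-B profile ("matched" mode, `n`
#' coefficients); "all_pairs" mode correlates all `n x n` cross-tissue
#' pairs. Between-tissue means are also computed per CpG density class
#' on the corresponding probe subsets.
#'
#' @param data A [matched_dataset()].
#' @param between_mode `"matched"` (default) or `"all_pairs"`.
#' @return A list of class `correlation_summary`: vectors `within_a`,
#'   `within_b`, `between`, their means, `between_by_class` (named mean
#'   per CpG class) and the `between_mode` used.
#' @export
samplewise_correlations <- function(data, between_mode = c("matched",
                                                           "all_pairs")) {
  stopifnot(inherits(data, "matched_dataset"))
  between_mode <- match.arg(between_mode)
  A <- data$tissue_a$beta
  B <- data$tissue_b$beta
  if (nrow(A) < 2 || ncol(A) < 2)
    stop("need at least 2 probes and 2 subjects", call. = FALSE)

  upper <- function(m) m[upper.tri(m)]
  within_a <- upper(stats::cor(A))
  within_b <- upper(stats::cor(B))

  between_for <- function(Asub, Bsub) {
    cc <- stats::cor(Asub, Bsub)
    if (between_mode == "matched") diag(cc) else as.vector(cc)
  }
  between <- between_for(A, B)

  classes <- data$annotation$cpg_class
  by_class <- vapply(CPG_CLASSES, function(cl) {
    idx <- which(classes == cl)
    if (length(idx) < 2) return(NA_real_)
    mean(between_for(A[idx, , drop = FALSE], B[idx, , drop = FALSE]))
  }, numeric(1))

  structure(list(within_a = within_a, within_b = within_b, between = between,
                 mean_within_a = mean(within_a),
                 mean_within_b = mean(within_b),
                 mean_between = mean(between),
                 between_by_class = by_class,
                 between_mode = between_mode),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("correlation_summary (between mode: %s)\n", x$between_mode))
  cat(sprintf("  mean within A:  %.3f\n", x$mean_within_a))
  cat(sprintf("  mean within B:  %.3f\n", x$mean_within_b))
  cat(sprintf("  mean between:   %.3f\n", x$mean_between))
  cat("  between by class:",
      paste(sprintf("%s=%.3f", names(x$between_by_class), x$between_by_class),
            collapse = " "), "\n")
  invisible(x)
}

#' Global paired test of tissue methylation level
#'
#' Collapses each tissue to one mean beta per subject (over all retained
#' probes) and tests the matched per-subject means with a two-tailed
#' exact Wilcoxon signed-rank test (zero differences dropped by the
#' signed-rank convention). Also reports how many subjects have a higher
#' tissue-B than tissue-A mean.
#'
#' @param data A [matched_dataset()].
#' @return List: `subject_means` (data frame subject/mean_a/mean_b),
#'   `statistic`, `p`, `n_b_greater`, `n_nonzero`.
#' @export
global_tissue_test <- function(data) {
  stopifnot(inherits(data, "matched_dataset"))
  if (n_subjects(data) < 5)
    stop("global test needs at least 5 subjects", call. = FALSE)
  mean_a <- colMeans(data$tissue_a$beta)
  mean_b <- colMeans(data$tissue_b$beta)
  d <- mean_b - mean_a
  nonzero <- sum(d != 0)
  if (nonzero == 0) {
    stat <- NA_real_; p <- NA_real_
    message("all paired subject means are identical; global test undefined")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(mean_b, mean_a, paired = TRUE,
                                              alternative = "two.sided",
                                              exact = TRUE))
    stat <- unname(wt$statistic)
    p <- wt$p.value
  }
  list(subject_means = data.frame(subject_id = data$subject_order,
                                  mean_a = unname(mean_a),
                                  mean_b = unname(mean_b),
                                  stringsAsFactors = FALSE),
       statistic = stat, p = p,
       n_b_greater = sum(d > 0), n_nonzero = nonzero)
}
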
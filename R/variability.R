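#' Mean-normalize per-subject beta values
#'
#' Centers a probe's values on their subject mean so ranges can be
#' compared across probes; outputs sum to zero.
#'
#' @param betas Numeric vector of per-subject values for one probe.
#' @return Centered values.
#' @export
mean_normalize <- function(betas) {
  if (length(betas) < 2) stop("need at least 2 subjects", call. = FALSE)
  betas - mean(betas)
}

#' Inter-individual range of a probe
#'
#' @param betas Numeric vector of per-subject beta values.
#' @return `max - min`.
#' @export
probe_range <- function(betas) {
  if (length(betas) < 2) stop("need at least 2 subjects", call. = FALSE)
  max(betas) - min(betas)
}

#' Variance-stabilizing transform of beta values
#'
#' Beta values truncate variance near 0 and 1; the default transform is
#' the base-2 logit `log2(beta / (1 - beta))` (the M-value of the
#' methylation literature). An arcsine-square-root alternative
#' `asin(sqrt(beta))` is available. Both are strictly monotone on
#' (0, 1). Betas of exactly 0 or 1 are rejected: run
#' [replace_zeros()] (or cap symmetrically) first.
#'
#' @param beta Numeric vector/matrix of beta values strictly inside (0, 1).
#' @param method `"logit"` (default) or `"arcsine"`.
#' @return Transformed values (same shape).
#' @examples
#' beta_transform(0.5)  # 0
#' beta_transform(0.8)  # 2
#' @export
beta_transform <- function(beta, method = c("logit", "arcsine")) {
  method <- match.arg(method)
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly inside (0, 1); ",
         "replace zeros (see replace_zeros) or cap ones first", call. = FALSE)
  switch(method,
         logit = log2(beta / (1 - beta)),
         arcsine = asin(sqrt(beta)))
}

#' Inverse of [beta_transform()]
#'
#' @param m Transformed values.
#' @param method `"logit"` or `"arcsine"`.
#' @return Beta values in (0, 1).
#' @export
beta_inverse_transform <- function(m, method = c("logit", "arcsine")) {
  method <- match.arg(method)
  switch(method,
         logit = 2^m / (1 + 2^m),
         arcsine = sin(m)^2)
}

#' Levene / Brown-Forsythe test for equality of two variances
#'
#' Classic Levene W statistic on absolute deviations from the group
#' center, with p-value from the F distribution on
#' `(1, n_a + n_b - 2)` degrees of freedom. The default center is the
#' group median (the Brown-Forsythe variant, robust to non-normality);
#' mean centering is available.
#'
#' @param group_a,group_b Numeric vectors (transformed beta values of the
#'   two tissues for one probe), each of length >= 3.
#' @param center `"median"` (default) or `"mean"`.
#' @return Named numeric vector `c(stat, p)`; both groups degenerate
#'   (zero spread) gives `stat = 0, p = 1`.
#' @export
levene_test <- function(group_a, group_b, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs at least 3 values", call. = FALSE)
  cfun <- if (center == "median") stats::median else mean
  za <- abs(group_a - cfun(group_a))
  zb <- abs(group_b - cfun(group_b))
  na <- length(za); nb <- length(zb)
  N <- na + nb
  zbar_a <- mean(za); zbar_b <- mean(zb)
  zbar <- (na * zbar_a + nb * zbar_b) / N
  ss_between <- na * (zbar_a - zbar)^2 + nb * (zbar_b - zbar)^2
  ss_within <- sum((za - zbar_a)^2) + sum((zb - zbar_b)^2)
  if (ss_within == 0) {
    if (ss_between == 0) return(c(stat = 0, p = 1))
    return(c(stat = Inf, p = .Machine$double.xmin))
  }
  W <- (N - 2) * ss_between / ss_within
  c(stat = W, p = stats::pf(W, 1, N - 2, lower.tail = FALSE))
}

#' Variance-concordance classification with a relative band
#'
#' Taking tissue A's variance as the reference, a probe is within the
#' band when tissue B's variance lies in the closed interval
#' `[(1 - band) * var_a, (1 + band) * var_a]`.
#'
#' @param var_a,var_b Per-probe variances (any common scale).
#' @param band Relative half-width of the band (default 0.20).
#' @return Character vector in `c("within_band", "outside_band")`.
#' @export
variance_concordance <- function(var_a, var_b, band = 0.20) {
  n <- max(length(var_a), length(var_b))
  var_a <- rep_len(var_a, n)
  var_b <- rep_len(var_b, n)
  out <- rep_len("outside_band", n)
  zero_ref <- !is.na(var_a) & var_a == 0
  if (any(zero_ref))
    warning(sum(zero_ref), " probe(s) with zero reference variance ",
            "classified outside_band", call. = FALSE)
  ok <- !is.na(var_a) & !is.na(var_b) & var_a > 0
  out[ok & var_b >= (1 - band) * var_a & var_b <= (1 + band) * var_a] <-
    "within_band"
  out[is.na(var_a) | is.na(var_b)] <- NA_character_
  out
}

#' Highly variable loci by standard-deviation cutoff
#'
#' @param sd Named numeric vector of per-probe standard deviations on
#'   the raw beta scale (names are probe ids).
#' @param threshold SD cutoff; probes strictly above it are returned.
#' @return Character vector of probe ids.
#' @export
variable_loci <- function(sd, threshold) {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (is.null(names(sd))) stop("`sd` must be named by probe id", call. = FALSE)
  names(sd)[!is.na(sd) & sd > threshold]
}

#' Probe-wise cross-tissue Pearson correlation
#'
#' For each probe, the Pearson correlation between the n matched subject
#' values in tissue A and tissue B, with two-sided p from the t
#' transformation and Storey q-values across probes. Quantifies whether
#' a subject's relative methylation level at a probe is preserved
#' across tissues.
#'
#' @param data A [matched_dataset()].
#' @param r_flag Absolute-correlation cutoff reported as `good_r`
#'   (default 0.5).
#' @return Data frame per probe: `probe_id`, `cross_r`, `cross_p`,
#'   `cross_r_q`, `good_r`. Probes with zero variance in either tissue
#'   get `NA` and are excluded from the FDR.
#' @export
cross_tissue_probe_correlation <- function(data, r_flag = 0.5) {
  stopifnot(inherits(data, "matched_dataset"))
  n <- n_subjects(data)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  A <- data$tissue_a$beta
  B <- data$tissue_b$beta
  sd_a <- apply(A, 1, stats::sd)
  sd_b <- apply(B, 1, stats::sd)
  ok <- sd_a > 0 & sd_b > 0
  r <- rep(NA_real_, nrow(A))
  r[ok] <- vapply(which(ok), function(i) stats::cor(A[i, ], B[i, ]),
                  numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- .Machine$double.xmin
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- storey_qvalue(p[ok])$q
  data.frame(probe_id = rownames(A),
             cross_r = r, cross_p = p, cross_r_q = q,
             good_r = !is.na(r) & abs(r) > r_flag,
             stringsAsFactors = FALSE)
}

#' Probe-wise variability and cross-tissue variance-concordance table
#'
#' For every probe: inter-individual range and SD per tissue on the raw
#' beta scale, variances of the transformed values, the Levene /
#' Brown-Forsythe equality-of-variance test with Benjamini-Hochberg
#' adjustment, the variance ratio (tissue B over tissue A) with its
#' concordance-band class, and the cross-tissue Pearson correlation.
#' Zeros are replaced per tissue before transformation.
#'
#' @param data A [matched_dataset()] (post QC).
#' @param band Relative variance band (default 0.20), applied on the
#'   transformed scale by default.
#' @param transform `"logit"` or `"arcsine"`, see [beta_transform()].
#' @param center Levene centering, `"median"` or `"mean"`.
#' @param band_scale `"transformed"` (default) or `"raw"`: the scale on
#'   which the concordance band is evaluated.
#' @return Data frame with one row per probe (see fields above), plus
#'   attributes `transform` and `band_scale` recording the modes used.
#' @export
variability <- function(data, band = 0.20, transform = c("logit", "arcsine"),
                        center = c("median", "mean"),
                        band_scale = c("transformed", "raw")) {
  stopifnot(inherits(data, "matched_dataset"))
  transform <- match.arg(transform)
  center <- match.arg(center)
  band_scale <- match.arg(band_scale)
  A <- replace_zeros(data$tissue_a)$beta
  B <- replace_zeros(data$tissue_b)$beta
  TA <- beta_transform(A, transform)
  TB <- beta_transform(B, transform)

  lev <- vapply(seq_len(nrow(A)),
                function(i) levene_test(TA[i, ], TB[i, ], center),
                numeric(2))
  var_t_a <- apply(TA, 1, stats::var)
  var_t_b <- apply(TB, 1, stats::var)
  var_raw_a <- apply(A, 1, stats::var)
  var_raw_b <- apply(B, 1, stats::var)
  if (band_scale == "transformed") {
    conc <- variance_concordance(var_t_a, var_t_b, band)
    ratio <- var_t_b / var_t_a
  } else {
    conc <- variance_concordance(var_raw_a, var_raw_b, band)
    ratio <- var_raw_b / var_raw_a
  }
  cross <- cross_tissue_probe_correlation(data)

  out <- data.frame(probe_id = rownames(A),
                    cpg_class = data$annotation$cpg_class,
                    range_a = apply(A, 1, probe_range),
                    range_b = apply(B, 1, probe_range),
                    sd_a = sqrt(var_raw_a),
                    sd_b = sqrt(var_raw_b),
                    var_t_a = var_t_a,
                    var_t_b = var_t_b,
                    levene_stat = unname(lev["stat", ]),
                    levene_p = unname(lev["p", ]),
                    levene_p_bh = bh_adjust(lev["p", ]),
                    variance_ratio = ratio,
                    concordance = conc,
                    cross_r = cross$cross_r,
                    cross_p = cross$cross_p,
                    cross_r_q = cross$cross_r_q,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "transform") <- transform
  attr(out, "band_scale") <- band_scale
  out
}
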
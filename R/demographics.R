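#' Rank-sum association of one probe with a binary variable
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test of the per-subject beta
#' values between the two groups (exact when the combined n is below 50
#' and there are no ties, normal approximation with continuity
#' correction otherwise). The effect is the difference of group mean
#' betas (second group level minus first).
#'
#' @param betas Numeric vector of per-subject beta values for one probe.
#' @param groups Vector (factor, character or logical) with exactly two
#'   levels, one per subject.
#' @return Named numeric vector `c(statistic, p, effect)`.
#' @examples
#' ranksum_association(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
ranksum_association <- function(betas, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("`groups` must have exactly two levels", call. = FALSE)
  g1 <- betas[groups == levels(groups)[1]]
  g2 <- betas[groups == levels(groups)[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("both groups need at least 2 members", call. = FALSE)
  effect <- mean(g2) - mean(g1)
  if (length(unique(betas)) == 1)
    return(c(statistic = length(g1) * length(g2) / 2, p = 1, effect = effect))
  wt <- suppressWarnings(stats::wilcox.test(g1, g2,
                                            alternative = "two.sided"))
  c(statistic = unname(wt$statistic), p = min(wt$p.value, 1), effect = effect)
}

#' Pearson association of one probe with a continuous covariate
#'
#' Pearson correlation with two-sided p-value from the t transformation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param betas Numeric vector of per-subject beta values for one probe.
#' @param covariate Numeric vector (age, BMI, ...), same subjects.
#' @return Named numeric vector `c(r, p)`.
#' @export
pearson_association <- function(betas, covariate) {
  if (length(betas) != length(covariate))
    stop("`betas` and `covariate` must have equal length", call. = FALSE)
  n <- length(betas)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(covariate) == 0)
    stop("`covariate` is constant", call. = FALSE)
  if (stats::sd(betas) == 0) return(c(r = NA_real_, p = NA_real_))
  r <- stats::cor(betas, covariate)
  if (abs(r) == 1) return(c(r = r, p = .Machine$double.xmin))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion `pi0` from `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))` over a lambda grid, smoothed
#' with a cubic spline and evaluated at the largest lambda, then
#' converts p-values to q-values by the step-up rule
#' `q_(i) = min_{j >= i} min(1, pi0 * m * p_(j) / j)`. For fewer than
#' 100 p-values the smoother is unstable and a fixed `lambda = 0.5`
#' estimate is used instead. `pi0` is clamped to (0, 1]; with
#' `pi0 = 1` the q-values equal Benjamini-Hochberg adjusted p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda_grid Grid for pi0 estimation (default `seq(0.05, 0.95,
#'   0.05)`).
#' @param pi0 Optional fixed null proportion overriding estimation.
#' @return List with `q` (q-values in input order) and `pi0` (the
#'   estimate used).
#' @export
storey_qvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), pi0 = NA_real_))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (anyNA(p))
    stop("missing p-values; drop them before FDR correction", call. = FALSE)
  if (is.null(pi0)) {
    if (m < 100) {
      lam <- 0.5
      pi0 <- sum(p > lam) / (m * (1 - lam))
    } else {
      lam <- sort(lambda_grid)
      pi0_lam <- vapply(lam, function(l) sum(p > l) / (m * (1 - l)),
                        numeric(1))
      fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
      pi0 <- stats::predict(fit, x = max(lam))$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("`pi0` must lie in (0, 1]", call. = FALSE)
  }
  o <- order(p)
  q_sorted <- pmin(1, pi0 * m * p[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' P-value distribution diagnostics for one association scan
#'
#' Summarizes the shape of an unadjusted p-value distribution: a
#' histogram at bin width 0.05, the fraction below 0.05, the one-sample
#' Kolmogorov-Smirnov statistic against Uniform(0, 1) and the Storey
#' pi0 estimate. Left skew (excess mass in the low bins) indicates a
#' higher likelihood of true association even when no individual probe
#' survives FDR.
#'
#' @param p Numeric vector of p-values.
#' @param variable Name of the scanned variable (carried through).
#' @return A one-row data frame plus a `histogram` attribute of 20 bin
#'   counts.
#' @export
pvalue_diagnostics <- function(p, variable = NA_character_) {
  p <- p[!is.na(p)]
  breaks <- seq(0, 1, by = 0.05)
  counts <- as.integer(table(cut(p, breaks, include.lowest = TRUE)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  out <- data.frame(variable = variable,
                    n = length(p),
                    frac_below_05 = mean(p < 0.05),
                    ks_stat = unname(ks$statistic),
                    pi0_hat = storey_qvalue(p)$pi0,
                    stringsAsFactors = FALSE)
  attr(out, "histogram") <- counts
  out
}

#' Probe-wise association scan of demographic variables in one tissue
#'
#' For each requested variable, runs the appropriate test on every
#' probe of the chosen tissue — rank-sum for categorical (binary)
#' variables, Pearson correlation for continuous ones — and corrects
#' with Storey q-values. The significance call is `q <= q_threshold`.
#' For categorical variables the effect is the difference of group mean
#' betas; for continuous variables the reported `effect_delta_beta` is
#' the fitted beta difference between the lowest and highest covariate
#' value under the least-squares line, so the "effect > 5%" style
#' filter applies to both kinds of variable.
#'
#' @param data A [matched_dataset()].
#' @param tissue `"a"` or `"b"`: which tissue to scan.
#' @param variables Character vector of sample-sheet columns (default
#'   the standard demographic set present in the sheet among
#'   `age, sex, ethnicity, bmi, alcohol`).
#' @param tests Optional named character vector overriding the test per
#'   variable (`"ranksum"` or `"pearson"`); by default factor/character
#'   columns get rank-sum, numeric columns Pearson.
#' @param q_threshold Significance cutoff on the q-value (default 0.05,
#'   boundary inclusive).
#' @param effect_threshold `|delta beta|` cutoff reported alongside
#'   (default 0.05).
#' @return List of class `association_scan`: `results` (data frame
#'   probe x variable), `diagnostics` (one row per variable),
#'   `summary` (counts per variable), `tissue`.
#' @export
association_scan <- function(data, tissue = c("b", "a"), variables = NULL,
                             tests = NULL, q_threshold = 0.05,
                             effect_threshold = 0.05) {
  stopifnot(inherits(data, "matched_dataset"))
  tissue <- match.arg(tissue)
  beta <- if (tissue == "a") data$tissue_a$beta else data$tissue_b$beta
  tissue_label <- data$tissue_labels[[tissue]]
  sheet <- data$samples[data$samples$tissue == tissue_label, , drop = FALSE]
  sheet <- sheet[match(data$subject_order, sheet$subject_id), , drop = FALSE]

  if (is.null(variables))
    variables <- intersect(c("age", "sex", "ethnicity", "bmi", "alcohol"),
                           names(sheet))
  missing <- setdiff(variables, names(sheet))
  if (length(missing) > 0)
    stop("variable(s) not in sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)

  results <- list()
  diagnostics <- list()
  summary_rows <- list()
  for (v in variables) {
    values <- sheet[[v]]
    ok_subj <- !is.na(values)
    values <- values[ok_subj]
    test <- if (!is.null(tests) && v %in% names(tests)) tests[[v]] else if
      (is.numeric(values)) "pearson" else "ranksum"
    if (test == "ranksum" && length(unique(values)) != 2) {
      warning(sprintf("variable '%s' does not have two levels; skipped", v),
              call. = FALSE)
      next
    }
    if (test == "pearson" && stats::sd(values) == 0) {
      warning(sprintf("variable '%s' is constant; skipped", v), call. = FALSE)
      next
    }
    b <- beta[, ok_subj, drop = FALSE]
    if (test == "ranksum") {
      groups <- as.factor(values)
      res <- vapply(seq_len(nrow(b)),
                    function(i) ranksum_association(b[i, ], groups),
                    numeric(3))
      stat <- res["statistic", ]; p <- res["p", ]
      effect <- res["effect", ]
    } else {
      res <- vapply(seq_len(nrow(b)),
                    function(i) pearson_association(b[i, ], values),
                    numeric(2))
      stat <- res["r", ]; p <- res["p", ]
      # fitted beta change across the observed covariate span
      span <- max(values) - min(values)
      slope <- vapply(seq_len(nrow(b)), function(i) {
        stats::cov(b[i, ], values) / stats::var(values)
      }, numeric(1))
      effect <- slope * span
    }
    tested <- !is.na(p)
    q <- rep(NA_real_, length(p))
    sq <- storey_qvalue(p[tested])
    q[tested] <- sq$q
    tab <- data.frame(probe_id = rownames(beta), variable = v, test = test,
                      statistic = stat, effect_delta_beta = effect,
                      p = p, q = q,
                      significant = !is.na(q) & q <= q_threshold,
                      stringsAsFactors = FALSE)
    results[[v]] <- tab
    diagnostics[[v]] <- pvalue_diagnostics(p, v)
    summary_rows[[v]] <- data.frame(
      variable = v, test = test, n_tested = sum(tested),
      n_significant = sum(tab$significant),
      n_significant_large_effect =
        sum(tab$significant & abs(tab$effect_delta_beta) > effect_threshold),
      pi0_hat = sq$pi0,
      stringsAsFactors = FALSE)
  }
  structure(list(results = do.call(rbind, c(results, make.row.names = FALSE)),
                 diagnostics = do.call(rbind, c(diagnostics,
                                                make.row.names = FALSE)),
                 summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 tissue = tissue, tissue_label = tissue_label,
                 q_threshold = q_threshold),
            class = "association_scan")
}

#' @export
print.association_scan <- function(x, ...) {
  cat(sprintf("association_scan: tissue %s, q <= %g\n",
              x$tissue_label, x$q_threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
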
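#' Percentage with one decimal, rounded half-up
#'
#' All reported percentages use round-half-up at one decimal (so
#' 537/998 prints 53.8 and 0.25 would print 0.3), matching the usual
#' reporting convention rather than R's banker's rounding.
#'
#' @param count,total Nonnegative integers, `count <= total`, `total > 0`.
#' @return `100 * count / total` rounded half-up to one decimal.
#' @examples
#' percentage(537, 998)  # 53.8
#' @export
percentage <- function(count, total) {
  if (any(total <= 0)) stop("`total` must be positive", call. = FALSE)
  if (any(count < 0 | count > total))
    stop("`count` must lie in [0, total]", call. = FALSE)
  floor(1000 * count / total + 0.5) / 10
}

#' Run the full matched-tissue methylation pipeline
#'
#' Executes the stages in fixed order on a matched dataset: probe QC
#' (filters + zero replacement), probe-wise tissue specificity (paired
#' t, BH, delta-beta classes, ICC), methylation categories, sample-wise
#' correlation structure, the global paired tissue test, probe-wise
#' variability (ranges, SD cutoffs, Levene/Brown-Forsythe, variance
#' concordance, cross-tissue correlation), CpG-density enrichment of
#' the tissue-specific and variable-loci sets, and demographic
#' association scans in both tissues. Returns every stage table plus a
#' machine-readable run summary of counts and percentages.
#'
#' @param data A [matched_dataset()] (pre-QC), e.g. from
#'   [align_matched()] or [simulate_cohort()].
#' @param qc [qc_config()] for the filtering stage.
#' @param p_threshold,delta_specific,delta_high Tissue-specificity
#'   cutoffs, see [classify_specificity()].
#' @param sd_thresholds SD cutoffs defining variable loci.
#' @param band Variance-concordance band.
#' @param variables Demographic variables to scan (default: those
#'   present in the sample sheet).
#' @param out_dir Optional directory; when given, per-stage TSV tables
#'   and a JSON run summary are written there.
#' @return A list of class `methmatch_run`: `data` (post-QC),
#'   `qc_report`, `specificity`, `categories`, `correlations`,
#'   `global_test`, `variability`, `variable_loci`, `enrichment`,
#'   `associations` (per tissue), `summary`.
#' @export
run_pipeline <- function(data, qc = qc_config(),
                         p_threshold = 0.001, delta_specific = 0.2,
                         delta_high = 0.4, sd_thresholds = c(0.1, 0.3),
                         band = 0.20, variables = NULL, out_dir = NULL) {
  stopifnot(inherits(data, "matched_dataset"))

  filtered <- filter_probes(data, qc)
  ds <- filtered$data
  ds$tissue_a <- replace_zeros(ds$tissue_a)
  ds$tissue_b <- replace_zeros(ds$tissue_b)

  spec <- tissue_specificity(ds, p_threshold, delta_specific, delta_high)
  categories <- data.frame(
    probe_id = rep(spec$probe_id, 2),
    tissue = rep(unname(ds$tissue_labels[c("a", "b")]),
                 each = nrow(spec)),
    category = c(methylation_category(spec$mean_beta_a),
                 methylation_category(spec$mean_beta_b)),
    stringsAsFactors = FALSE)
  correlations <- samplewise_correlations(ds)
  global_test <- global_tissue_test(ds)
  vr <- variability(ds, band = band)

  loci <- list()
  for (thr in sd_thresholds) {
    loci[[paste0("a_sd", thr)]] <-
      variable_loci(stats::setNames(vr$sd_a, vr$probe_id), thr)
    loci[[paste0("b_sd", thr)]] <-
      variable_loci(stats::setNames(vr$sd_b, vr$probe_id), thr)
  }

  enrich <- list()
  ts_probes <- spec$probe_id[spec$spec_class != "none"]
  if (length(ts_probes) > 0)
    enrich$tissue_specific <- enrichment_scan(ts_probes, ds$annotation)
  for (nm in names(loci))
    if (length(loci[[nm]]) > 0)
      enrich[[paste0("variable_", nm)]] <- enrichment_scan(loci[[nm]],
                                                           ds$annotation)

  assoc <- list(a = association_scan(ds, "a", variables),
                b = association_scan(ds, "b", variables))

  np <- nrow(spec)
  n_ts <- sum(spec$spec_class != "none")
  n_hts <- sum(spec$spec_class == "highly_tissue_specific")
  n_sig_p <- sum(spec$p_bh < p_threshold)
  lev_sig <- !is.na(vr$levene_p_bh) & vr$levene_p_bh < 0.05
  n_within <- sum(vr$concordance == "within_band", na.rm = TRUE)
  n_outside <- sum(vr$concordance == "outside_band", na.rm = TRUE)
  cat_frac <- function(tissue_label) {
    cc <- categories$category[categories$tissue == tissue_label]
    counts <- table(factor(cc, levels = c("hypomethylated", "heterogeneous",
                                          "hypermethylated")))
    stats::setNames(percentage(as.integer(counts), np), names(counts))
  }
  summary <- list(
    n_probes_input = filtered$report$n_input,
    n_probes_analyzed = np,
    methylation_categories = lapply(
      stats::setNames(unname(ds$tissue_labels), names(ds$tissue_labels)),
      cat_frac),
    n_significant_p = n_sig_p,
    n_tissue_specific = n_ts,
    pct_tissue_specific = percentage(n_ts, np),
    n_highly_tissue_specific = n_hts,
    pct_highly_tissue_specific = percentage(n_hts, np),
    mean_within_a = correlations$mean_within_a,
    mean_within_b = correlations$mean_within_b,
    mean_between = correlations$mean_between,
    between_by_class = as.list(correlations$between_by_class),
    global_test_p = global_test$p,
    n_subjects_b_greater = global_test$n_b_greater,
    variable_loci = lapply(loci, length),
    pct_variable_loci = lapply(loci, function(x) percentage(length(x), np)),
    n_unequal_variance = sum(lev_sig),
    pct_unequal_variance = percentage(sum(lev_sig), np),
    n_unequal_larger_a = sum(lev_sig & vr$var_t_a > vr$var_t_b),
    n_unequal_larger_b = sum(lev_sig & vr$var_t_b > vr$var_t_a),
    n_within_band = n_within,
    n_outside_band = n_outside,
    n_band_undefined = np - n_within - n_outside,
    n_good_cross_r = sum(abs(vr$cross_r) > 0.5, na.rm = TRUE),
    n_cross_r_q25 = sum(abs(vr$cross_r) > 0.5 & vr$cross_r_q <= 0.25,
                        na.rm = TRUE),
    n_cross_r_q05 = sum(abs(vr$cross_r) > 0.5 & vr$cross_r_q <= 0.05,
                        na.rm = TRUE),
    associations = lapply(assoc, function(x) x$summary))

  run <- structure(list(data = ds, qc_report = filtered$report,
                        specificity = spec, categories = categories,
                        correlations = correlations,
                        global_test = global_test,
                        variability = vr, variable_loci = loci,
                        enrichment = enrich, associations = assoc,
                        summary = summary),
                   class = "methmatch_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.methmatch_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("methmatch_run: %d probes analyzed (%d in)\n",
              s$n_probes_analyzed, s$n_probes_input))
  cat(sprintf("  tissue specific: %d (%.1f%%), highly: %d (%.1f%%)\n",
              s$n_tissue_specific, s$pct_tissue_specific,
              s$n_highly_tissue_specific, s$pct_highly_tissue_specific))
  cat(sprintf("  mean r within A/within B/between: %.3f / %.3f / %.3f\n",
              s$mean_within_a, s$mean_within_b, s$mean_between))
  cat(sprintf("  unequal variance (Levene BH<0.05): %d (%.1f%%); band: %d within / %d outside\n",
              s$n_unequal_variance, s$pct_unequal_variance,
              s$n_within_band, s$n_outside_band))
  invisible(x)
}

#' Write every stage output of a pipeline run
#'
#' Emits per-stage TSV tables and a JSON run summary under `dir`.
#'
#' @param run A `methmatch_run` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "methmatch_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(run$specificity, file.path(dir, "tissue_specificity.tsv"))
  write_results(run$variability, file.path(dir, "variability.tsv"))
  write_results(run$categories, file.path(dir, "methylation_categories.tsv"))
  if (length(run$enrichment) > 0)
    write_results(do.call(rbind, c(lapply(names(run$enrichment), function(nm) {
      cbind(subset_name = nm, run$enrichment[[nm]])
    }), make.row.names = FALSE)), file.path(dir, "enrichment.tsv"))
  for (t in names(run$associations))
    write_results(run$associations[[t]]$results,
                  file.path(dir, paste0("associations_", t, ".tsv")))
  removed <- run$qc_report$removed
  if (length(removed) > 0 && sum(lengths(removed)) > 0)
    write_results(data.frame(
      probe_id = unlist(removed, use.names = FALSE),
      reason = rep(names(removed), lengths(removed))),
      file.path(dir, "qc_removed.tsv"))
  jsonlite::write_json(
    list(qc = list(n_input = run$qc_report$n_input,
                   n_retained = run$qc_report$n_retained,
                   removed = lapply(run$qc_report$removed, length)),
         summary = run$summary),
    file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}
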
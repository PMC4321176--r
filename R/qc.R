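#' Probe-level quality-control configuration
#'
#' Defaults follow common practice for promoter CpG panels on a matched
#' cohort: drop SNP-overlapping probes, sex-chromosome probes and
#' polymorphic CpGs; drop probes where almost every subject (more than
#' `n_subjects - 2`) reports a beta of exactly zero in either tissue; and
#' drop probes where more than `max_detection_failures` subjects fail
#' background detection in either tissue.
#'
#' @param drop_snp_probes,drop_sex_chromosomes,drop_polymorphic Logical
#'   switches for the annotation-driven filters.
#' @param max_zero_subjects Probes with strictly more than this many
#'   zero-beta subjects (per tissue) are removed; `NULL` means
#'   `n_subjects - 2`, resolved when filtering. Set to `Inf` to disable.
#' @param max_detection_failures Probes with strictly more than this many
#'   subjects above `detection_alpha` (per tissue) are removed; `NULL`
#'   disables the rule.
#' @param detection_alpha Detection p-value above which a measurement
#'   counts as below background.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(drop_snp_probes = TRUE,
                      drop_sex_chromosomes = TRUE,
                      drop_polymorphic = TRUE,
                      max_zero_subjects = NULL,
                      max_detection_failures = 3L,
                      detection_alpha = 0.05) {
  if (!is.null(max_zero_subjects) && max_zero_subjects < 0)
    stop("`max_zero_subjects` must be nonnegative", call. = FALSE)
  if (!is.null(max_detection_failures) && max_detection_failures < 0)
    stop("`max_detection_failures` must be nonnegative", call. = FALSE)
  if (detection_alpha < 0 || detection_alpha > 1)
    stop("`detection_alpha` must be in [0, 1]", call. = FALSE)
  structure(list(drop_snp_probes = drop_snp_probes,
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 drop_polymorphic = drop_polymorphic,
                 max_zero_subjects = max_zero_subjects,
                 max_detection_failures = max_detection_failures,
                 detection_alpha = detection_alpha),
            class = "qc_config")
}

#' Apply probe-level quality-control filters to a matched dataset
#'
#' Removes probes violating any enabled rule from both tissues
#' simultaneously: (1) SNP overlap, (2) sex chromosome, (3) polymorphic
#' CpG, (4) too many subjects with beta exactly zero in either tissue,
#' (5) too many subjects failing background detection in either tissue.
#' Count rules use strict inequalities ("more than k subjects"), so a
#' probe with exactly `max_detection_failures` failures is retained.
#'
#' @param data A [matched_dataset()].
#' @param config A [qc_config()].
#' @return A list with elements `data` (the filtered `matched_dataset`)
#'   and `report` (class `qc_report`: removed-probe lists per reason and
#'   the input/retained counts).
#' @export
filter_probes <- function(data, config = qc_config()) {
  stopifnot(inherits(data, "matched_dataset"))
  if (!inherits(config, "qc_config")) stop("`config` must be a qc_config",
                                           call. = FALSE)
  ann <- data$annotation
  probes <- ann$probe_id
  n <- n_subjects(data)
  removed <- list()

  if (isTRUE(config$drop_snp_probes))
    removed$snp_overlap <- probes[ann$snp_overlap]
  if (isTRUE(config$drop_sex_chromosomes))
    removed$sex_chromosome <- probes[is_sex_chromosome(ann$chromosome)]
  if (isTRUE(config$drop_polymorphic))
    removed$polymorphic_cpg <- probes[ann$polymorphic_cpg]

  max_zero <- config$max_zero_subjects
  if (is.null(max_zero)) max_zero <- n - 2L
  if (is.finite(max_zero)) {
    zeros_a <- rowSums(data$tissue_a$beta == 0, na.rm = TRUE)
    zeros_b <- rowSums(data$tissue_b$beta == 0, na.rm = TRUE)
    removed$zero_beta <- probes[zeros_a > max_zero | zeros_b > max_zero]
  }

  if (!is.null(config$max_detection_failures)) {
    if (is.null(data$tissue_a$detection_p) || is.null(data$tissue_b$detection_p))
      stop("detection p-values are absent; disable the detection rule with ",
           "qc_config(max_detection_failures = NULL)", call. = FALSE)
    fail_a <- rowSums(data$tissue_a$detection_p > config$detection_alpha,
                      na.rm = TRUE)
    fail_b <- rowSums(data$tissue_b$detection_p > config$detection_alpha,
                      na.rm = TRUE)
    removed$detection_failure <-
      probes[fail_a > config$max_detection_failures |
             fail_b > config$max_detection_failures]
  }

  drop <- unique(unlist(removed, use.names = FALSE))
  keep <- setdiff(probes, drop)
  if (length(keep) == 0)
    stop("quality control removed every probe", call. = FALSE)

  report <- structure(list(removed = removed,
                           n_input = length(probes),
                           n_retained = length(keep)),
                      class = "qc_report")
  out <- matched_dataset(
    tissue_a = subset_beta_matrix(data$tissue_a, keep),
    tissue_b = subset_beta_matrix(data$tissue_b, keep),
    annotation = ann[ann$probe_id %in% keep, , drop = FALSE],
    samples = data$samples,
    subject_order = data$subject_order,
    tissue_labels = data$tissue_labels)
  list(data = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d probes in, %d retained, %d removed\n",
              x$n_input, x$n_retained, x$n_input - x$n_retained))
  for (reason in names(x$removed))
    cat(sprintf("  %-18s %d\n", reason, length(x$removed[[reason]])))
  invisible(x)
}

#' Replace zero beta values with the tissue minimum
#'
#' Every beta of exactly zero is replaced by the minimum strictly
#' positive beta observed anywhere in the same tissue's matrix (in the
#' motivating study, 0.033 for PBMC and 0.03 for BEC), so the logit
#' transform is defined everywhere. All other values are untouched;
#' the operation is idempotent.
#'
#' @param matrix A [beta_matrix()] for one tissue, already filtered.
#' @return The `beta_matrix` with zeros replaced.
#' @export
replace_zeros <- function(matrix) {
  stopifnot(inherits(matrix, "beta_matrix"))
  beta <- matrix$beta
  pos <- beta[!is.na(beta) & beta > 0]
  if (length(pos) == 0)
    stop("all beta values are zero; cannot determine a replacement minimum",
         call. = FALSE)
  beta[!is.na(beta) & beta == 0] <- min(pos)
  beta_matrix(beta, matrix$detection_p)
}
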
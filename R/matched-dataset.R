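#' Construct a matched two-tissue methylation dataset
#'
#' A `matched_dataset` holds two subject-aligned [beta_matrix()] objects
#' (one per tissue), a probe annotation table and a sample sheet. Both
#' tissues carry the same probes in the same order, and column `j` of
#' either tissue belongs to subject `subject_order[j]`, so paired
#' statistics can index the two matrices in lockstep.
#'
#' @param tissue_a,tissue_b [beta_matrix()] objects with identical probe
#'   order; columns ordered by `subject_order`.
#' @param annotation Probe annotation data frame covering every probe
#'   (see [validate_annotation()]); reordered to probe order.
#' @param samples Sample sheet data frame (see [validate_sample_sheet()]).
#' @param subject_order Character vector of subject ids giving the shared
#'   column order.
#' @param tissue_labels Named character vector `c(a = ..., b = ...)`
#'   recording the original tissue names (e.g. BEC, PBMC).
#' @return An object of class `matched_dataset`.
#' @seealso [align_matched()] which builds one from unaligned inputs.
#' @export
matched_dataset <- function(tissue_a, tissue_b, annotation, samples,
                            subject_order,
                            tissue_labels = c(a = "A", b = "B")) {
  stopifnot(inherits(tissue_a, "beta_matrix"), inherits(tissue_b, "beta_matrix"))
  if (!identical(rownames(tissue_a$beta), rownames(tissue_b$beta)))
    stop("the two tissues must carry identical probe ids in identical order",
         call. = FALSE)
  subject_order <- as.character(subject_order)
  if (anyDuplicated(subject_order))
    stop("duplicate subject ids in `subject_order`", call. = FALSE)
  if (ncol(tissue_a$beta) != length(subject_order) ||
      ncol(tissue_b$beta) != length(subject_order))
    stop("each tissue must have exactly one sample column per subject",
         call. = FALSE)
  annotation <- validate_annotation(annotation)
  probes <- rownames(tissue_a$beta)
  if (!all(probes %in% annotation$probe_id))
    stop("annotation does not cover every probe (first missing: ",
         setdiff(probes, annotation$probe_id)[1], ")", call. = FALSE)
  annotation <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  rownames(annotation) <- NULL
  samples <- validate_sample_sheet(samples)
  structure(list(tissue_a = tissue_a, tissue_b = tissue_b,
                 annotation = annotation, samples = samples,
                 subject_order = subject_order,
                 tissue_labels = tissue_labels),
            class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat(sprintf("matched_dataset: %d probes x %d subjects x 2 tissues (%s, %s)\n",
              nrow(x$tissue_a$beta), length(x$subject_order),
              x$tissue_labels[["a"]], x$tissue_labels[["b"]]))
  tab <- table(factor(x$annotation$cpg_class, levels = CPG_CLASSES))
  cat("CpG density classes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

#' Number of matched subjects in a dataset
#' @param data A `matched_dataset`.
#' @export
n_subjects <- function(data) length(data$subject_order)

#' Align two tissue beta matrices into a matched dataset
#'
#' Reorders probes to a common order (tissue A's order restricted to the
#' shared probe universe), maps sample columns to subjects through the
#' sample sheet, and keeps the subjects present in both tissues. Subjects
#' missing one tissue are dropped with a warning; probes absent from one
#' tissue are dropped silently (intersection).
#'
#' @param a,b [beta_matrix()] objects for the two tissues.
#' @param samples Sample sheet mapping `sample_id` to `subject_id` and
#'   `tissue`.
#' @param annotation Probe annotation table covering the shared probes.
#' @param tissue_levels Length-2 character vector naming which `tissue`
#'   value of the sample sheet is tissue A and which is B; defaults to
#'   the sorted unique tissue labels.
#' @return A [matched_dataset()].
#' @export
align_matched <- function(a, b, samples, annotation, tissue_levels = NULL) {
  stopifnot(inherits(a, "beta_matrix"), inherits(b, "beta_matrix"))
  samples <- validate_sample_sheet(samples)
  if (is.null(tissue_levels)) tissue_levels <- sort(unique(samples$tissue))
  if (length(tissue_levels) != 2)
    stop("exactly two tissue labels required, got: ",
         paste(tissue_levels, collapse = ", "), call. = FALSE)

  probes <- intersect(rownames(a$beta), rownames(b$beta))
  if (length(probes) == 0)
    stop("no overlapping probes between the two tissues", call. = FALSE)

  sheet_a <- samples[samples$tissue == tissue_levels[1], , drop = FALSE]
  sheet_b <- samples[samples$tissue == tissue_levels[2], , drop = FALSE]
  sheet_a <- sheet_a[sheet_a$sample_id %in% colnames(a$beta), , drop = FALSE]
  sheet_b <- sheet_b[sheet_b$sample_id %in% colnames(b$beta), , drop = FALSE]

  subjects <- intersect(sheet_a$subject_id, sheet_b$subject_id)
  if (length(subjects) == 0)
    stop("no subjects present in both tissues", call. = FALSE)
  dropped <- setdiff(union(sheet_a$subject_id, sheet_b$subject_id), subjects)
  if (length(dropped) > 0)
    warning(sprintf("dropping %d subject(s) missing one tissue: %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
  # keep the sample-sheet order of tissue-A subjects
  subjects <- sheet_a$subject_id[sheet_a$subject_id %in% subjects]

  cols_a <- sheet_a$sample_id[match(subjects, sheet_a$subject_id)]
  cols_b <- sheet_b$sample_id[match(subjects, sheet_b$subject_id)]

  matched_dataset(
    tissue_a = subset_beta_matrix(a, probes, cols_a),
    tissue_b = subset_beta_matrix(b, probes, cols_b),
    annotation = annotation,
    samples = samples[samples$subject_id %in% subjects, , drop = FALSE],
    subject_order = subjects,
    tissue_labels = c(a = tissue_levels[1], b = tissue_levels[2]))
}
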
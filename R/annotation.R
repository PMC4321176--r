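#' CpG-island density classes
#'
#' Probe annotation levels used throughout the package: high (HC),
#' intermediate (IC) and low (LC) CpG density, plus "uncategorized" for
#' probes with no island metrics and no preassigned class.
#' @keywords internal
CPG_CLASSES <- c("HC", "IC", "LC", "uncategorized")

#' Classify a CpG region by island density
#'
#' Applies the standard three-way CpG-island density classification from
#' GC content, observed/expected CpG ratio and island length. A region is
#' HC (high density) when GC content > 0.55, Obs/Exp CpG ratio > 0.75 and
#' length > 500 bp; otherwise IC (intermediate) when GC content > 0.50,
#' Obs/Exp > 0.48 and length > 200 bp; otherwise LC (low density /
#' non-island). Inequalities are strict, so boundary values fall through
#' to the weaker class. The HC rule is tested first; a region satisfying
#' both rule sets is HC.
#'
#' @param gc_content GC content as a fraction in \[0, 1\].
#' @param obs_exp Observed/expected CpG ratio (nonnegative).
#' @param length Island length in base pairs (nonnegative).
#' @return Character vector over `gc_content` etc. with values in
#'   `c("HC", "IC", "LC")`; `NA` inputs yield `"uncategorized"`.
#' @examples
#' derive_cpg_class(0.60, 0.80, 600)  # "HC"
#' derive_cpg_class(0.52, 0.50, 300)  # "IC"
#' derive_cpg_class(0.40, 0.20, 100)  # "LC"
#' @export
derive_cpg_class <- function(gc_content, obs_exp, length) {
  n <- max(length(gc_content), length(obs_exp), length(length))
  gc_content <- rep_len(gc_content, n)
  obs_exp <- rep_len(obs_exp, n)
  length <- rep_len(length, n)
  if (any(gc_content < 0 | obs_exp < 0 | length < 0, na.rm = TRUE))
    stop("island metrics must be nonnegative", call. = FALSE)
  if (any(gc_content > 1, na.rm = TRUE))
    stop("`gc_content` must be a fraction in [0, 1]", call. = FALSE)
  out <- rep_len("uncategorized", n)
  ok <- !is.na(gc_content) & !is.na(obs_exp) & !is.na(length)
  out[ok] <- "LC"
  ic <- ok & gc_content > 0.50 & obs_exp > 0.48 & length > 200
  out[ic] <- "IC"
  hc <- ok & gc_content > 0.55 & obs_exp > 0.75 & length > 500
  out[hc] <- "HC"
  out
}

#' Validate (and complete) a probe annotation table
#'
#' Checks the probe annotation data frame used by the pipeline:
#' `probe_id` unique; `cpg_class` in HC/IC/LC/uncategorized (filled from
#' island metrics via [derive_cpg_class()] when absent); logical
#' `snp_overlap` and `polymorphic_cpg` flags (defaulting to `FALSE` when
#' missing). Chromosome names are free text and passed through.
#'
#' @param annotation Data frame with at least a `probe_id` column;
#'   recognised optional columns: `chromosome`, `gene_symbol`,
#'   `cpg_class`, `gc_content`, `obs_exp_cpg_ratio`, `island_length`,
#'   `snp_overlap`, `polymorphic_cpg`.
#' @return The annotation data frame with `cpg_class`, `snp_overlap`,
#'   `polymorphic_cpg` and `chromosome` columns guaranteed present.
#' @export
validate_annotation <- function(annotation) {
  if (!is.data.frame(annotation) || !"probe_id" %in% names(annotation))
    stop("annotation must be a data frame with a `probe_id` column", call. = FALSE)
  annotation$probe_id <- as.character(annotation$probe_id)
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(utils::head(unique(
           annotation$probe_id[duplicated(annotation$probe_id)]), 5),
           collapse = ", "), call. = FALSE)
  if (!"cpg_class" %in% names(annotation)) {
    if (all(c("gc_content", "obs_exp_cpg_ratio", "island_length") %in%
            names(annotation))) {
      annotation$cpg_class <- derive_cpg_class(
        annotation$gc_content, annotation$obs_exp_cpg_ratio,
        annotation$island_length)
    } else {
      annotation$cpg_class <- "uncategorized"
    }
  }
  annotation$cpg_class <- as.character(annotation$cpg_class)
  annotation$cpg_class[is.na(annotation$cpg_class)] <- "uncategorized"
  bad <- setdiff(unique(annotation$cpg_class), CPG_CLASSES)
  if (length(bad) > 0)
    stop("unknown cpg_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (flag in c("snp_overlap", "polymorphic_cpg")) {
    if (!flag %in% names(annotation)) annotation[[flag]] <- FALSE
    annotation[[flag]] <- as.logical(annotation[[flag]])
    annotation[[flag]][is.na(annotation[[flag]])] <- FALSE
  }
  if (!"chromosome" %in% names(annotation)) annotation$chromosome <- NA_character_
  annotation
}

#' Identify sex-chromosome annotations
#'
#' @param chromosome Character vector of chromosome names; "X"/"Y"
#'   matching is case-insensitive and tolerant of a "chr" prefix.
#' @return Logical vector, `NA` treated as not sex-linked.
#' @keywords internal
is_sex_chromosome <- function(chromosome) {
  chr <- toupper(sub("^chr", "", as.character(chromosome), ignore.case = TRUE))
  !is.na(chr) & chr %in% c("X", "Y")
}
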
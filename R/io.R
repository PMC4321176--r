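# All delimited I/O is tab-separated UTF-8 with "." decimal and "NA" for
# missing values; floats are written at fixed precision so repeated writes
# of the same table are byte-identical.

BETA_WRITE_DIGITS <- 10L

#' Read a beta-value matrix from delimited text
#'
#' Expects tab-separated text with probe ids in the first column and a
#' header row of sample ids; all remaining cells numeric beta values in
#' \[0, 1\]. An optional companion file of detection p-values must have
#' the identical shape and ids.
#'
#' @param path Path to the beta-value table.
#' @param detection_path Optional path to a same-shape detection p-value
#'   table.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_path = NULL) {
  beta <- read_numeric_matrix(path)
  dp <- NULL
  if (!is.null(detection_path)) {
    dp <- read_numeric_matrix(detection_path)
    if (!identical(dim(dp), dim(beta)) ||
        !identical(rownames(dp), rownames(beta)))
      stop("detection p-value table does not match the beta table ",
           "(probe ids/shape differ)", call. = FALSE)
    dp <- dp[, colnames(beta), drop = FALSE]
  }
  beta_matrix(beta, dp)
}

read_numeric_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 1) stop("no sample columns in ", path, call. = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric cell(s) in column '%s' of %s",
                   names(df)[j], path), call. = FALSE)
  }
  as.matrix(df)
}

#' Write a beta-value matrix (and detection p-values) to delimited text
#'
#' @param x A [beta_matrix()].
#' @param path Output path for the beta table.
#' @param detection_path Optional output path for the detection p-values.
#' @param digits Decimal digits for numeric cells.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(x, path, detection_path = NULL,
                              digits = BETA_WRITE_DIGITS) {
  write_numeric_matrix(x$beta, path, digits)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p))
      stop("no detection p-values to write", call. = FALSE)
    write_numeric_matrix(x$detection_p, detection_path, digits)
  }
  invisible(path)
}

write_numeric_matrix <- function(m, path, digits = BETA_WRITE_DIGITS) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  body <- apply(format_fixed(m, digits), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

format_fixed <- function(x, digits) {
  out <- formatC(x, digits = digits, format = "g", flag = "#")
  out <- sub("\\.$", "", sub("0+$", "", out))
  out[is.na(x)] <- "NA"
  dim(out) <- dim(x)
  out
}

#' Write a per-probe result table to delimited text
#'
#' Tab-separated with header, one row per probe, rows in input order,
#' numeric columns at fixed precision so two writes of the same table are
#' byte-identical.
#'
#' @param table Nonempty data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path, digits = BETA_WRITE_DIGITS) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("`table` must be a nonempty data frame", call. = FALSE)
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format_fixed(out[[j]], digits)
    else if (is.logical(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", ifelse(out[[j]], "TRUE", "FALSE"))
    else {
      out[[j]] <- as.character(out[[j]])
      out[[j]][is.na(out[[j]])] <- "NA"
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a tab-separated table with header.
#' @return A data frame; numeric-looking columns are parsed as numeric.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a sample sheet
#'
#' Delimited text with one row per (subject, tissue) sample. Required
#' columns: `sample_id`, `subject_id`, `tissue`; typical demographic
#' columns: `age`, `sex`, `ethnicity`, `bmi`, `alcohol`.
#'
#' @param path Path to the sample sheet (tab- or comma-separated; the
#'   separator is sniffed from the header line).
#' @return A validated data frame.
#' @export
read_sample_sheet <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_sample_sheet(df)
}

#' Validate a sample sheet
#'
#' @param samples Data frame with `sample_id`, `subject_id`, `tissue`
#'   columns; `(subject_id, tissue)` must be unique; `age` and `bmi`,
#'   when present, must be positive.
#' @return The validated data frame (ids coerced to character).
#' @export
validate_sample_sheet <- function(samples) {
  req <- c("sample_id", "subject_id", "tissue")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in req) samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  key <- paste(samples$subject_id, samples$tissue, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, tissue) pairs in sample sheet", call. = FALSE)
  if ("age" %in% names(samples) && any(samples$age <= 0, na.rm = TRUE))
    stop("ages must be positive", call. = FALSE)
  if ("bmi" %in% names(samples) && any(samples$bmi <= 0, na.rm = TRUE))
    stop("BMI values must be positive", call. = FALSE)
  samples
}

#' Read a probe annotation table
#'
#' @param path Path to a tab-separated annotation table with a `probe_id`
#'   column; see [validate_annotation()] for recognised columns.
#' @return A validated annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_annotation(df)
}
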
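#' Construct a beta-value matrix for one tissue
#'
#' A `beta_matrix` holds probe x sample DNA methylation fractions (beta
#' values, the methylated proportion of signal at a CpG site) for a single
#' tissue, optionally together with a same-shape matrix of detection
#' p-values. Probes are rows, samples are columns; both must carry unique
#' ids as dimnames.
#'
#' @param beta Numeric matrix of methylation fractions in \[0, 1\] with
#'   probe ids as rownames and sample ids as colnames.
#' @param detection_p Optional numeric matrix of detection p-values in
#'   \[0, 1\], same shape and dimnames as `beta`. Large values flag
#'   measurements indistinguishable from array background.
#' @return An object of class `beta_matrix`: a list with elements `beta`
#'   and `detection_p` (possibly `NULL`).
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bm <- beta_matrix(m)
#' probe_ids(bm)
#' @export
beta_matrix <- function(beta, detection_p = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("`beta` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must have probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s' (value %g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !is.numeric(detection_p))
      stop("`detection_p` must be a numeric matrix", call. = FALSE)
    if (!identical(dim(detection_p), dim(beta)))
      stop(sprintf("detection p-value matrix shape (%d x %d) does not match beta matrix (%d x %d)",
                   nrow(detection_p), ncol(detection_p), nrow(beta), ncol(beta)),
           call. = FALSE)
    if (!is.null(rownames(detection_p)) &&
        !identical(rownames(detection_p), rownames(beta)))
      stop("detection p-value rownames do not match beta probe ids", call. = FALSE)
    if (any(!is.na(detection_p) & (detection_p < 0 | detection_p > 1)))
      stop("detection p-values must lie in [0, 1]", call. = FALSE)
    dimnames(detection_p) <- dimnames(beta)
  }
  structure(list(beta = beta, detection_p = detection_p),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  invisible(x)
}

#' @rdname beta_matrix
#' @param x A `beta_matrix` or `matched_dataset`.
#' @export
probe_ids <- function(x) UseMethod("probe_ids")

#' @export
probe_ids.beta_matrix <- function(x) rownames(x$beta)

#' @export
probe_ids.matched_dataset <- function(x) rownames(x$tissue_a$beta)

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' Subset a beta matrix by probe and/or sample ids
#'
#' @param x A `beta_matrix`.
#' @param probes,samples Character vectors of ids to retain, in the order
#'   given; `NULL` keeps all.
#' @return A `beta_matrix` restricted (and reordered) to the requested ids.
#' @keywords internal
subset_beta_matrix <- function(x, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- rownames(x$beta)
  if (is.null(samples)) samples <- colnames(x$beta)
  missing_p <- setdiff(probes, rownames(x$beta))
  if (length(missing_p) > 0)
    stop("unknown probe ids: ", paste(utils::head(missing_p, 5), collapse = ", "),
         call. = FALSE)
  beta <- x$beta[probes, samples, drop = FALSE]
  dp <- if (is.null(x$detection_p)) NULL else
    x$detection_p[probes, samples, drop = FALSE]
  beta_matrix(beta, dp)
}
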
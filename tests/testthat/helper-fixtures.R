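# Small constructors used across the test files. Everything is built in
# code; no fixture files.

rand_beta <- function(n_probes, n_samples, prefix = "s") {
  m <- matrix(stats::runif(n_probes * n_samples, 0.01, 0.99),
              n_probes, n_samples,
              dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                              paste0(prefix, seq_len(n_samples))))
  beta_matrix(m)
}

# matched_dataset straight from two value matrices (probes x subjects)
make_matched <- function(a, b, classes = NULL, chromosome = NULL,
                         snp = NULL, poly = NULL,
                         det_a = NULL, det_b = NULL, sheet_extra = NULL) {
  np <- nrow(a)
  n <- ncol(a)
  probes <- rownames(a)
  if (is.null(probes)) probes <- sprintf("cg%03d", seq_len(np))
  subj <- sprintf("S%02d", seq_len(n))
  dimnames(a) <- list(probes, paste0(subj, "_A"))
  dimnames(b) <- list(probes, paste0(subj, "_B"))
  if (!is.null(det_a)) dimnames(det_a) <- dimnames(a)
  if (!is.null(det_b)) dimnames(det_b) <- dimnames(b)
  ann <- data.frame(
    probe_id = probes,
    chromosome = if (is.null(chromosome)) rep("chr1", np) else chromosome,
    cpg_class = if (is.null(classes)) rep("uncategorized", np) else classes,
    snp_overlap = if (is.null(snp)) rep(FALSE, np) else snp,
    polymorphic_cpg = if (is.null(poly)) rep(FALSE, np) else poly,
    stringsAsFactors = FALSE)
  sheet <- data.frame(
    sample_id = c(paste0(subj, "_A"), paste0(subj, "_B")),
    subject_id = rep(subj, 2),
    tissue = rep(c("A", "B"), each = n),
    stringsAsFactors = FALSE)
  if (!is.null(sheet_extra))
    sheet <- cbind(sheet, sheet_extra[rep(seq_len(n), 2), , drop = FALSE])
  matched_dataset(beta_matrix(a, det_a), beta_matrix(b, det_b),
                  ann, sheet, subj)
}

# small-cohort simulation config used where full size is not needed
small_config <- function(seed, n_probes = 300L,
                         planted_assoc = list(sex = list(n_probes = 20L,
                                                         effect = 0.15,
                                                         tissue = "b")),
                         ...) {
  simulation_config(
    n_probes = n_probes, seed = seed,
    planted_assoc = planted_assoc,
    qc_artifacts = c(snp = 4L, x_chromosome = 3L, polymorphic = 2L,
                     zero_heavy = 2L, detection_failure = 3L),
    ...)
}
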
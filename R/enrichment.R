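#' One-tailed hypergeometric tail probability
#'
#' Probability of the observed category overlap under random sampling
#' without replacement: with `X ~ Hypergeometric(N, K, n)`, enrichment
#' is the upper tail and depletion the lower tail. By default the
#' observed count is included in the tail (`P(X >= k)` / `P(X <= k)`),
#' the proper one-sided p-value. `include_observed = FALSE` gives the
#' exclusive upper tail `P(X > k)` (and for depletion `P(X < k)`), a
#' convention some published analyses use for enrichment.
#'
#' @param k Observed overlap (subset probes in the category).
#' @param K Category size in the population.
#' @param N Population size (all analyzed probes).
#' @param n Subset size.
#' @param direction `"enrichment"` or `"depletion"`.
#' @param include_observed Include `k` itself in the tail (default TRUE).
#' @return The tail probability.
#' @examples
#' hypergeom_tail(2, 2, 4, 2, "enrichment")  # 1/6
#' @export
hypergeom_tail <- function(k, K, N, n,
                           direction = c("enrichment", "depletion"),
                           include_observed = TRUE) {
  direction <- match.arg(direction)
  if (K > N || n > N) stop("`K` and `n` cannot exceed `N`", call. = FALSE)
  if (k < 0 || k > min(K, n))
    stop("`k` must satisfy 0 <= k <= min(K, n)", call. = FALSE)
  if (direction == "enrichment") {
    q <- if (include_observed) k - 1 else k
    stats::phyper(q, K, N - K, n, lower.tail = FALSE)
  } else {
    q <- if (include_observed) k else k - 1
    stats::phyper(q, K, N - K, n, lower.tail = TRUE)
  }
}

#' Hypergeometric enrichment scan over CpG density classes
#'
#' Tests a probe subset for enrichment or depletion in each CpG density
#' class. The population is every probe in the annotation (uncategorized
#' probes count toward `N` but are not themselves a tested category by
#' default). The direction is chosen per category by comparing the
#' observed overlap `k` with its expectation `n * K / N`: above gives an
#' enrichment (upper-tail) test, below a depletion (lower-tail) test;
#' `k` equal to its expectation is reported as enrichment and flagged
#' degenerate.
#'
#' @param subset Character vector of probe ids (must all be in the
#'   annotation).
#' @param annotation Probe annotation data frame (the analyzed universe).
#' @param categories CpG classes to test (default `c("LC", "IC", "HC")`).
#' @param include_observed Tail convention, see [hypergeom_tail()].
#' @param bh Apply Benjamini-Hochberg across the tested categories
#'   (default FALSE; the primary convention is unadjusted).
#' @return Data frame with one row per category: `category`,
#'   `population_n`, `category_k`, `sample_n`, `overlap`, `expected`,
#'   `direction`, `p` (and `p_bh` when `bh = TRUE`), `degenerate`.
#' @export
enrichment_scan <- function(subset, annotation,
                            categories = c("LC", "IC", "HC"),
                            include_observed = TRUE, bh = FALSE) {
  annotation <- validate_annotation(annotation)
  subset <- unique(as.character(subset))
  if (length(subset) == 0) stop("`subset` is empty", call. = FALSE)
  missing <- setdiff(subset, annotation$probe_id)
  if (length(missing) > 0)
    stop("subset probe(s) not in the analyzed universe: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  N <- nrow(annotation)
  n <- length(subset)
  in_subset <- annotation$probe_id %in% subset
  rows <- lapply(categories, function(cl) {
    K <- sum(annotation$cpg_class == cl)
    k <- sum(in_subset & annotation$cpg_class == cl)
    expected <- n * K / N
    direction <- if (k >= expected) "enrichment" else "depletion"
    data.frame(category = cl, population_n = N, category_k = K,
               sample_n = n, overlap = k, expected = expected,
               direction = direction,
               p = hypergeom_tail(k, K, N, n, direction, include_observed),
               degenerate = k == expected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- bh_adjust(out$p)
  out
}
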
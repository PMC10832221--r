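# Preranked gene-set enrichment on a weighted Kolmogorov-Smirnov running
# sum (weight exponent 1), with a seeded permutation p-value or, when the
# number of same-size sets is small, exact enumeration.

#' Weighted KS enrichment score for a set of list positions
#'
#' The list is assumed ranked (position 1 = top). Hits advance the running
#' sum by |weight| / sum(|weights in set|); misses retreat by 1 / (n - k).
#' The statistic is the maximum of the running sum (one-sided, positive
#' deviations). A set covering the whole list has ES = 1.
#'
#' @param positions integer positions of the set members in the ranked list.
#' @param weights numeric weights of ALL list elements, in rank order.
#' @return the enrichment score.
#' @export
gsea_es <- function(positions, weights) {
  n <- length(weights)
  k <- length(positions)
  if (k == 0L) sponge_abort("empty set", "empty_input_error")
  positions <- sort.int(positions)
  w <- abs(weights[positions])
  W <- sum(w)
  hit <- if (W == 0) cumsum(rep(1 / k, k)) else cumsum(w) / W
  miss <- if (n == k) rep(0, k) else (positions - seq_len(k)) / (n - k)
  # the running sum attains its maximum immediately after a hit
  max(hit - miss)
}

#' Permutation / exact p-value for a preranked enrichment score
#'
#' One-sided for positive enrichment. If the number of equally likely sets
#' `choose(n, k)` does not exceed `exact_limit`, the p-value is computed by
#' exhaustive enumeration: the fraction of same-size sets with ES at least
#' the observed one. Otherwise `nperm` random sets are drawn and
#' p = (1 + #{ES_perm >= ES_obs}) / (nperm + 1).
#'
#' @param positions,weights as in [gsea_es()].
#' @param nperm number of random sets for the sampled mode.
#' @param exact_limit enumeration budget (default 1e5 combinations).
#' @return list with `es`, `pvalue`, `exact` (logical), `n`, `k`.
#' @export
gsea_pvalue <- function(positions, weights, nperm = 10000L, exact_limit = 1e5) {
  n <- length(weights)
  k <- length(positions)
  es <- gsea_es(positions, weights)
  if (k == n) {
    # the set owns every element: a single possible configuration
    return(list(es = es, pvalue = 1, exact = TRUE, n = n, k = k))
  }
  eps <- 1e-12
  if (choose(n, k) <= exact_limit) {
    combos <- utils::combn(n, k)
    hits <- sum(apply(combos, 2L, function(pos) gsea_es(pos, weights) >= es - eps))
    return(list(es = es, pvalue = hits / ncol(combos), exact = TRUE, n = n, k = k))
  }
  hits <- 0L
  for (b in seq_len(nperm)) {
    if (gsea_es(sample.int(n, k), weights) >= es - eps) hits <- hits + 1L
  }
  list(es = es, pvalue = (1 + hits) / (nperm + 1), exact = FALSE, n = n, k = k)
}
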
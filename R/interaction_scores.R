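# Per-pair interaction reliability scores. Raw context scores follow the
# TargetScan convention: lower (more negative) = stronger predicted binding.

#' Collapse per-site rows to per-pair records
#'
#' One output row per (miRNA, target): `n_sites` counts the MREs and
#' `raw_score_best` is the most favourable (minimum, i.e. strongest) raw
#' context score among the pair's sites.
#'
#' @param sites a [site_table()].
#' @return data.frame with columns `mirna_id`, `target_id`, `target_type`,
#'   `raw_score_best`, `n_sites`.
#' @export
collapse_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_type = character(0), raw_score_best = numeric(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  }
  key <- interaction(sites$mirna_id, sites$target_id, drop = TRUE, lex.order = TRUE)
  agg <- data.frame(mirna_id = tapply(sites$mirna_id, key, `[`, 1L),
                    target_id = tapply(sites$target_id, key, `[`, 1L),
                    target_type = sites$target_type[1L],
                    raw_score_best = as.numeric(tapply(sites$score, key, min)),
                    n_sites = as.integer(tapply(sites$score, key, length)),
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$mirna_id, agg$target_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Calibrate the affinity cutoff against validated interactions
#'
#' Restricts the predicted per-pair best scores to pairs present in the
#' validated table with at least `min_clip` CLIP-seq and `min_degradome`
#' degradome-seq experiments, then takes the stated percentile of that score
#' distribution (linear interpolation). Downstream, predicted pairs are kept
#' iff `raw_score_best <= cutoff` (binding at least as strong as the cutoff).
#'
#' @param predicted collapsed circRNA pair table from [collapse_sites()].
#' @param validated a [validated_table()].
#' @param percentile percentile of the restricted distribution (default 95).
#' @param min_clip,min_degradome minimum experimental evidence counts.
#' @return list with `cutoff`, `percentile`, `n_validated_used`.
#' @export
calibrate_affinity_cutoff <- function(predicted, validated, percentile = 95,
                                      min_clip = 2L, min_degradome = 2L) {
  ok <- validated[validated$n_clipseq >= min_clip &
                    validated$n_degradome >= min_degradome, , drop = FALSE]
  vkey <- paste(ok$mirna_id, ok$circ_id, sep = "\r")
  pkey <- paste(predicted$mirna_id, predicted$target_id, sep = "\r")
  scores <- predicted$raw_score_best[pkey %in% vkey]
  if (length(scores) == 0L) {
    sponge_abort(sprintf(
      "no validated interaction with >= %d CLIP-seq and >= %d degradome-seq experiments matches a predicted pair",
      min_clip, min_degradome), "calibration_error")
  }
  cutoff <- unname(stats::quantile(scores, percentile / 100, type = 7))
  sponge_log("affinity cutoff: %.4g (%gth percentile of %d validated pair scores)",
             cutoff, percentile, length(scores))
  list(cutoff = cutoff, percentile = percentile, n_validated_used = length(scores))
}

#' Apply a calibrated affinity cutoff
#'
#' @param pairs collapsed pair table.
#' @param cutoff result of [calibrate_affinity_cutoff()] or a plain number.
#' @return the pair rows with `raw_score_best <= cutoff`.
#' @export
apply_affinity_cutoff <- function(pairs, cutoff) {
  if (is.list(cutoff)) cutoff <- cutoff$cutoff
  out <- pairs[pairs$raw_score_best <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  sponge_log("affinity cutoff kept %d / %d pairs", nrow(out), nrow(pairs))
  out
}

#' Rescale raw context scores to S_Affinity in [0, 1]
#'
#' Min-max rescaling within the supplied table: the strongest (most negative)
#' raw score maps to 1, the weakest to 0. When all raw scores are equal the
#' degenerate convention assigns 0.5 everywhere. circRNA and mRNA tables are
#' rescaled independently (context+ and context++ scores share no scale).
#'
#' @param pairs collapsed pair table.
#' @return the table with an `s_affinity` column added.
#' @export
rescale_affinity <- function(pairs) {
  if (nrow(pairs) == 0L) {
    pairs$s_affinity <- numeric(0)
    return(pairs)
  }
  lo <- min(pairs$raw_score_best)
  hi <- max(pairs$raw_score_best)
  pairs$s_affinity <- if (hi == lo) rep(0.5, nrow(pairs)) else {
    (hi - pairs$raw_score_best) / (hi - lo)
  }
  pairs
}

#' Length-normalised MRE counts (S_NbMRE)
#'
#' circRNA targets: sites per nucleotide of spliced sequence. mRNA targets:
#' the raw site count (no length normalisation).
#'
#' @param pairs collapsed pair table.
#' @param lengths named length vector from [circ_length_table()]; required
#'   for circRNA tables.
#' @return the table with an `s_nbmre` column added.
#' @export
normalize_mre_counts <- function(pairs, lengths = NULL) {
  if (nrow(pairs) == 0L) {
    pairs$s_nbmre <- numeric(0)
    return(pairs)
  }
  if (pairs$target_type[1L] == "mRNA") {
    pairs$s_nbmre <- as.numeric(pairs$n_sites)
    return(pairs)
  }
  absent <- setdiff(unique(pairs$target_id), names(lengths))
  if (length(absent)) {
    sponge_abort(sprintf("no spliced length for circRNA(s): %s",
                         paste(absent, collapse = ", ")),
                 "missing_length_error")
  }
  pairs$s_nbmre <- pairs$n_sites / as.numeric(lengths[pairs$target_id])
  pairs
}

#' Binomial MRE enrichment per (miRNA, circRNA) pair (S_EnrichMRE)
#'
#' For pair (m, c): k = sites of m on c, N = all MRE sites on c, and the
#' background probability p0 = (sites of m on any circRNA) / (grand total of
#' sites on all circRNAs). The p-value is the one-sided upper tail
#' P(X >= k) for X ~ Binomial(N, p0); `s_enrichmre` is its BH adjustment
#' across all pairs tested in the run. Pairs with `s_enrichmre < alpha`
#' form the filtered output.
#'
#' @param circ_pairs collapsed circRNA pair table.
#' @param alpha significance threshold on the adjusted p-value (default 0.05).
#' @param drop_focal if `TRUE`, the focal miRNA's own sites are removed from
#'   the background when computing p0 (default `FALSE`).
#' @return list with `pairs` (input plus `s_enrichmre`) and `filtered`
#'   (rows with `s_enrichmre < alpha`).
#' @export
test_mre_enrichment <- function(circ_pairs, alpha = 0.05, drop_focal = FALSE) {
  if (nrow(circ_pairs) == 0L) {
    circ_pairs$s_enrichmre <- numeric(0)
    return(list(pairs = circ_pairs, filtered = circ_pairs))
  }
  grand <- sum(circ_pairs$n_sites)
  if (grand == 0L) {
    sponge_abort("no MRE sites on any circRNA: background is degenerate",
                 "degenerate_background_error")
  }
  per_circ <- tapply(circ_pairs$n_sites, circ_pairs$target_id, sum)
  per_mirna <- tapply(circ_pairs$n_sites, circ_pairs$mirna_id, sum)
  k <- circ_pairs$n_sites
  N <- as.integer(per_circ[circ_pairs$target_id])
  m_tot <- as.numeric(per_mirna[circ_pairs$mirna_id])
  p0 <- if (drop_focal) (m_tot - k) / (grand - k) else m_tot / grand
  pval <- stats::pbinom(k - 1L, N, p0, lower.tail = FALSE)
  circ_pairs$s_enrichmre <- bh_adjust(pval)
  filtered <- circ_pairs[circ_pairs$s_enrichmre < alpha, , drop = FALSE]
  rownames(filtered) <- NULL
  sponge_log("MRE enrichment: %d / %d pairs with BH-adjusted p < %g",
             nrow(filtered), nrow(circ_pairs), alpha)
  list(pairs = circ_pairs, filtered = filtered)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Textbook step-up: order the p-values, multiply the i-th smallest by n/i,
#' enforce monotonicity from the largest down, cap at 1. Kept in-package so
#' every BH family in the pipeline shares one exact implementation.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  ro <- p[o]
  adj <- pmin(1, rev(cummin(rev(ro * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Upper-tail binomial p-value
#'
#' Convenience wrapper: P(X >= k) for X ~ Binomial(N, p0); k = 0 gives 1.
#'
#' @param k observed successes.
#' @param N trials.
#' @param p0 success probability.
#' @return numeric vector of p-values.
#' @export
binomial_upper_tail <- function(k, N, p0) {
  stats::pbinom(k - 1L, N, p0, lower.tail = FALSE)
}
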
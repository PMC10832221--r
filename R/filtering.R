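#' Filter miRNAs by the pooled-Q1 sufficiency rule
#'
#' A miRNA is kept when (a) the sum of its expression over all samples is
#' nonzero and (b) its expression exceeds the cutoff in strictly more than
#' 90\% of its samples. The cutoff is the first quartile of the pooled value
#' distribution of the whole matrix (linear-interpolation quantile), zeros
#' included by default.
#'
#' When a [mirna_signature()] is supplied instead of a matrix the filter is
#' skipped: signatures are assumed pre-filtered by the same rule.
#'
#' @param mirna_expr miRNA [expression_matrix()] or [mirna_signature()].
#' @param fraction_threshold strict lower bound on the fraction of samples
#'   above the cutoff (default 0.9).
#' @param exclude_zeros if `TRUE`, zeros are removed from the pool before
#'   taking Q1 (default `FALSE`).
#' @return list with `kept_mirnas`, `cutoff`, `per_mirna_fraction`.
#' @export
filter_mirnas <- function(mirna_expr, fraction_threshold = 0.9,
                          exclude_zeros = FALSE) {
  if (inherits(mirna_expr, "sponge_signature")) {
    return(list(kept_mirnas = names(mirna_expr), cutoff = NA_real_,
                per_mirna_fraction = stats::setNames(rep(1, length(mirna_expr)),
                                                     names(mirna_expr)),
                skipped = TRUE))
  }
  if (nrow(mirna_expr) == 0L || ncol(mirna_expr) == 0L) {
    sponge_abort("miRNA expression matrix is empty", "empty_input_error")
  }
  pool <- as.numeric(mirna_expr)
  if (exclude_zeros) pool <- pool[pool != 0]
  cutoff <- unname(stats::quantile(pool, 0.25, type = 7))
  frac <- rowMeans(mirna_expr > cutoff)
  nonzero <- rowSums(mirna_expr) != 0
  kept <- rownames(mirna_expr)[nonzero & frac > fraction_threshold]
  sponge_log("miRNA sufficiency filter: Q1 cutoff = %.4g, kept %d / %d miRNAs",
             cutoff, length(kept), nrow(mirna_expr))
  list(kept_mirnas = kept, cutoff = cutoff,
       per_mirna_fraction = frac, skipped = FALSE)
}

#' Fold-change direction signs
#'
#' @param fc named numeric vector of log2 fold changes
#'   (condition_2 - condition_1), as returned by [compute_fold_change()].
#' @return named integer vector of signs: +1 up in condition_2, -1 up in
#'   condition_1, 0 when the fold change is exactly zero (such features are
#'   ineligible for any pair).
#' @export
split_by_direction <- function(fc) {
  stats::setNames(as.integer(sign(fc)), names(fc))
}

#' Apply the sponge-mechanism prerequisites
#'
#' Retains (miRNA, circRNA) pairs where the miRNA passed the sufficiency
#' filter, the circRNA has a nonzero fold-change direction, and the miRNA has
#' at least one mRNA target differentially expressed in the same direction as
#' the circRNA. The co-directional mRNA set is attached per pair.
#'
#' @param circ_pairs collapsed (and affinity-filtered) circRNA pair table.
#' @param mrna_pairs collapsed mRNA pair table.
#' @param kept result of [filter_mirnas()].
#' @param directions combined direction table covering circRNAs and mRNAs
#'   (from [split_by_direction()]).
#' @return data.frame with columns `mirna_id`, `circ_id`, `mrna_ids`
#'   (list-column of co-directional mRNA ids).
#' @export
apply_sponge_prerequisites <- function(circ_pairs, mrna_pairs, kept, directions) {
  dir_of <- function(ids) {
    d <- directions[ids]
    d[is.na(d)] <- 0L
    d
  }
  cp <- circ_pairs[circ_pairs$mirna_id %in% kept$kept_mirnas, , drop = FALSE]
  mp <- mrna_pairs[mrna_pairs$mirna_id %in% kept$kept_mirnas, , drop = FALSE]
  cp <- cp[dir_of(cp$target_id) != 0L, , drop = FALSE]
  mp <- mp[dir_of(mp$target_id) != 0L, , drop = FALSE]

  mrna_by_mirna_dir <- split(mp$target_id,
                             list(mirna = mp$mirna_id, dir = dir_of(mp$target_id)),
                             drop = TRUE)
  out <- list()
  for (i in seq_len(nrow(cp))) {
    key <- paste(cp$mirna_id[i], dir_of(cp$target_id[i]), sep = ".")
    mrnas <- mrna_by_mirna_dir[[key]]
    if (is.null(mrnas) || length(mrnas) == 0L) next
    out[[length(out) + 1L]] <- list(mirna_id = cp$mirna_id[i],
                                    circ_id = cp$target_id[i],
                                    mrna_ids = sort(unique(mrnas)))
  }
  if (length(out) == 0L) {
    sponge_log("sponge prerequisites: no eligible (miRNA, circRNA) pair remains")
    return(data.frame(mirna_id = character(0), circ_id = character(0),
                      mrna_ids = I(list()), stringsAsFactors = FALSE))
  }
  res <- data.frame(mirna_id = vapply(out, `[[`, character(1L), "mirna_id"),
                    circ_id = vapply(out, `[[`, character(1L), "circ_id"),
                    stringsAsFactors = FALSE)
  res$mrna_ids <- I(lapply(out, `[[`, "mrna_ids"))
  res <- res[order(res$mirna_id, res$circ_id), , drop = FALSE]
  rownames(res) <- NULL
  sponge_log("sponge prerequisites: %d eligible (miRNA, circRNA) pair(s)", nrow(res))
  res
}
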
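# SG scores for miRNA-mRNA pairs, the GSEA-based S_EnrichSG per miRNA, the
# sponge score SS per miRNA-circRNA pair, and the final 16-column matrix.

eligible_mrna_pairs <- function(eligible) {
  if (nrow(eligible) == 0L) {
    return(data.frame(mirna_id = character(0), mrna_id = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- mapply(function(m, targets) {
    data.frame(mirna_id = m, mrna_id = targets, stringsAsFactors = FALSE)
  }, eligible$mirna_id, eligible$mrna_ids, SIMPLIFY = FALSE)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global SG score for each eligible miRNA-mRNA pair
#'
#' One joint TOPSIS run over all eligible miRNA-mRNA pairs (the union of the
#' co-directional mRNA sets) with five benefit criteria: S_Affinity, S_NbMRE,
#' |S_FC| of the mRNA, S_MirExpr and S_TargetExpr of the mRNA.
#'
#' @param mrna_pairs scored mRNA pair table (with `s_affinity`, `s_nbmre`).
#' @param fc named fold-change vector covering the mRNAs.
#' @param mirexpr,targetexpr named score vectors (see
#'   [compute_mirna_expression_score()], [compute_target_expression_score()]).
#' @param eligible result of [apply_sponge_prerequisites()].
#' @param weights optional 5-vector of TOPSIS weights.
#' @param abs_fc use |S_FC| (default) rather than the signed value.
#' @return data.frame: `mirna_id`, `mrna_id`, the 5 criteria, `sg`.
#' @export
compute_sg <- function(mrna_pairs, fc, mirexpr, targetexpr, eligible,
                       weights = NULL, abs_fc = TRUE) {
  pairs <- eligible_mrna_pairs(eligible)
  if (nrow(pairs) == 0L) sponge_abort("no eligible miRNA-mRNA pair", "empty_input_error")
  key <- paste(mrna_pairs$mirna_id, mrna_pairs$target_id, sep = "\r")
  idx <- match(paste(pairs$mirna_id, pairs$mrna_id, sep = "\r"), key)
  if (anyNA(idx)) {
    sponge_abort("eligible miRNA-mRNA pair missing from the scored pair table",
                 "shape_error")
  }
  pairs$s_affinity <- mrna_pairs$s_affinity[idx]
  pairs$s_nbmre <- mrna_pairs$s_nbmre[idx]
  fcv <- fc[pairs$mrna_id]
  pairs$s_fc <- if (abs_fc) abs(fcv) else fcv
  pairs$s_mirexpr <- mirexpr[pairs$mirna_id]
  pairs$s_targetexpr <- targetexpr[pairs$mrna_id]
  crit <- as.matrix(pairs[, c("s_affinity", "s_nbmre", "s_fc",
                              "s_mirexpr", "s_targetexpr")])
  pairs$sg <- unname(topsis(crit, rep("benefit", 5L), weights))
  pairs
}

#' Per-miRNA enrichment of SG scores (S_EnrichSG)
#'
#' Ranks all miRNA-mRNA pairs by SG descending (ties broken by the stable
#' lexicographic (mirna_id, mrna_id) order); each miRNA's pairs form a set
#' whose concentration at the top of the list is scored by the weighted KS
#' enrichment statistic ([gsea_es()]) with the SG values as weights. The
#' p-value is exact (exhaustive enumeration) when feasible, otherwise a
#' seeded permutation estimate; BH adjustment across all miRNAs gives
#' `s_enrichsg`.
#'
#' @param sg result of [compute_sg()].
#' @param nperm permutations for the sampled mode (default 10000).
#' @param seed integer seed for the permutation draws.
#' @param exact_limit enumeration budget passed to [gsea_pvalue()].
#' @return data.frame: `mirna_id`, `es`, `pvalue`, `exact`, `s_enrichsg`.
#' @export
compute_enrich_sg <- function(sg, nperm = 10000L, seed = 1L, exact_limit = 1e5) {
  if (nrow(sg) == 0L) sponge_abort("no SG records", "empty_input_error")
  ord <- order(-sg$sg, sg$mirna_id, sg$mrna_id)
  ranked <- sg[ord, , drop = FALSE]
  weights <- ranked$sg
  mirnas <- sort(unique(ranked$mirna_id))
  set.seed(seed)
  res <- lapply(mirnas, function(m) {
    pos <- which(ranked$mirna_id == m)
    gsea_pvalue(pos, weights, nperm = nperm, exact_limit = exact_limit)
  })
  out <- data.frame(mirna_id = mirnas,
                    es = vapply(res, `[[`, numeric(1L), "es"),
                    pvalue = vapply(res, `[[`, numeric(1L), "pvalue"),
                    exact = vapply(res, `[[`, logical(1L), "exact"),
                    stringsAsFactors = FALSE)
  out$s_enrichsg <- bh_adjust(out$pvalue)
  out
}

#' Sponge score SS for each eligible miRNA-circRNA pair
#'
#' One joint TOPSIS run over all eligible pairs with seven criteria:
#' S_Affinity, S_NbMRE, S_MirExpr, S_TargetExpr of the circRNA and |S_FC| of
#' the circRNA as benefit criteria; the two adjusted enrichment p-values
#' S_EnrichSG and S_EnrichMRE as cost criteria.
#'
#' @param circ_pairs scored circRNA pair table (with `s_affinity`,
#'   `s_nbmre`, `s_enrichmre`).
#' @param fc named fold-change vector covering the circRNAs.
#' @param mirexpr,targetexpr named score vectors.
#' @param enrich_sg result of [compute_enrich_sg()].
#' @param eligible result of [apply_sponge_prerequisites()].
#' @param sg result of [compute_sg()], used for the per-pair mRNA summary
#'   columns.
#' @param weights optional 7-vector of TOPSIS weights.
#' @param abs_fc use |S_FC| (default) rather than the signed value.
#' @param neglog_costs enter the enrichment p-values as -log10(p) benefit
#'   criteria instead of raw cost criteria (default `FALSE`).
#' @return unranked score rows (one per eligible pair) with all criteria,
#'   `ss`, `condition` and the mRNA target summary.
#' @export
compute_sponge_scores <- function(circ_pairs, fc, mirexpr, targetexpr,
                                  enrich_sg, eligible, sg,
                                  weights = NULL, abs_fc = TRUE,
                                  neglog_costs = FALSE) {
  if (nrow(eligible) == 0L) sponge_abort("no eligible miRNA-circRNA pair", "empty_input_error")
  key <- paste(circ_pairs$mirna_id, circ_pairs$target_id, sep = "\r")
  idx <- match(paste(eligible$mirna_id, eligible$circ_id, sep = "\r"), key)
  if (anyNA(idx)) {
    sponge_abort("eligible miRNA-circRNA pair missing from the scored pair table",
                 "shape_error")
  }
  rows <- data.frame(mirna_id = eligible$mirna_id, circ_id = eligible$circ_id,
                     s_affinity = circ_pairs$s_affinity[idx],
                     s_nbmre = circ_pairs$s_nbmre[idx],
                     s_enrichmre = circ_pairs$s_enrichmre[idx],
                     s_fc_circ = unname(fc[eligible$circ_id]),
                     s_mirexpr = unname(mirexpr[eligible$mirna_id]),
                     s_targetexpr_circ = unname(targetexpr[eligible$circ_id]),
                     stringsAsFactors = FALSE)
  rows$s_enrichsg <- enrich_sg$s_enrichsg[match(rows$mirna_id, enrich_sg$mirna_id)]
  if (anyNA(rows$s_enrichsg)) {
    sponge_abort("missing S_EnrichSG for an eligible miRNA", "shape_error")
  }

  fc_crit <- if (abs_fc) abs(rows$s_fc_circ) else rows$s_fc_circ
  if (neglog_costs) {
    crit <- cbind(rows$s_affinity, rows$s_nbmre, rows$s_mirexpr,
                  rows$s_targetexpr_circ, fc_crit,
                  -log10(rows$s_enrichsg), -log10(rows$s_enrichmre))
    dirs <- rep("benefit", 7L)
  } else {
    crit <- cbind(rows$s_affinity, rows$s_nbmre, rows$s_mirexpr,
                  rows$s_targetexpr_circ, fc_crit,
                  rows$s_enrichsg, rows$s_enrichmre)
    dirs <- c(rep("benefit", 5L), "cost", "cost")
  }
  rows$ss <- unname(topsis(crit, dirs, weights))
  rows$condition <- ifelse(rows$s_fc_circ > 0, "condition_2", "condition_1")

  # per-pair mRNA summary from the co-directional target sets
  sg_key <- paste(sg$mirna_id, sg$mrna_id, sep = "\r")
  summ <- mapply(function(m, targets) {
    v <- sg$sg[match(paste(m, targets, sep = "\r"), sg_key)]
    list(n = length(targets), mean_sg = mean(v),
         lst = paste(targets, collapse = ";"))
  }, eligible$mirna_id, eligible$mrna_ids, SIMPLIFY = FALSE)
  rows$n_mrna_targets <- vapply(summ, function(s) as.integer(s$n), integer(1L))
  rows$mean_sg_of_targets <- vapply(summ, function(s) s$mean_sg, numeric(1L))
  rows$mrna_target_list <- vapply(summ, function(s) s$lst, character(1L))
  rownames(rows) <- NULL
  rows
}

#' Rank sponge scores and assemble the 16-column score matrix
#'
#' Global rank orders rows by SS descending with ties broken by the
#' lexicographic (mirna_id, circ_id) order; the per-condition rank repeats
#' this within each condition stratum (the strata partition the rows).
#'
#' @param rows result of [compute_sponge_scores()].
#' @return data.frame with exactly the 16 documented columns, sorted by
#'   `rank_global`.
#' @export
assemble_score_matrix <- function(rows) {
  if (nrow(rows) == 0L) {
    rows$rank_global <- integer(0)
    rows$rank_in_condition <- integer(0)
    return(rows[, score_matrix_columns, drop = FALSE])
  }
  ord <- order(-rows$ss, rows$mirna_id, rows$circ_id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank_global <- seq_len(nrow(rows))
  rows$rank_in_condition <- stats::ave(seq_len(nrow(rows)), rows$condition,
                                       FUN = seq_along)
  rows$rank_in_condition <- as.integer(rows$rank_in_condition)
  rownames(rows) <- NULL
  rows[, score_matrix_columns, drop = FALSE]
}
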
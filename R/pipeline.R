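#' Run configuration
#'
#' Collects every tunable constant of the pipeline. Defaults are the stated
#' method constants: Q1 sufficiency in > 90\% of samples, affinity cutoff at
#' the 95th percentile of validated-pair scores (>= 2 CLIP-seq and >= 2
#' degradome-seq experiments), MRE-enrichment threshold 0.05, network
#' truncation at the first 10\% of ranked targets.
#'
#' @param enrichmre_alpha BH-adjusted binomial threshold (default 0.05).
#' @param affinity_percentile percentile for the calibrated cutoff (95).
#' @param min_clip,min_degradome evidence minima for calibration (2, 2).
#' @param mirna_fraction_threshold strict sample-fraction bound (0.9).
#' @param target_fraction network truncation fraction (0.10).
#' @param nperm GSEA permutations (default 10000).
#' @param seed integer seed for the GSEA permutations (mandatory).
#' @param weights_sg,weights_ss optional TOPSIS weight vectors (5 and 7).
#' @param abs_fc use |S_FC| in TOPSIS (default TRUE).
#' @param mrna_cutoff also apply the calibrated affinity cutoff to
#'   miRNA-mRNA pairs (default FALSE; calibration is circRNA-based).
#' @param q1_excludes_zeros drop zeros from the Q1 pool (default FALSE).
#' @param neglog_costs enter enrichment p-values as -log10 benefits.
#' @param gsea_exact_limit enumeration budget for exact GSEA p-values.
#' @return list of class `sponge_config`.
#' @export
sponge_config <- function(enrichmre_alpha = 0.05, affinity_percentile = 95,
                          min_clip = 2L, min_degradome = 2L,
                          mirna_fraction_threshold = 0.9,
                          target_fraction = 0.10, nperm = 10000L, seed = 1L,
                          weights_sg = NULL, weights_ss = NULL,
                          abs_fc = TRUE, mrna_cutoff = FALSE,
                          q1_excludes_zeros = FALSE, neglog_costs = FALSE,
                          gsea_exact_limit = 1e5) {
  stopifnot(enrichmre_alpha > 0, enrichmre_alpha <= 1,
            affinity_percentile > 0, affinity_percentile <= 100,
            mirna_fraction_threshold >= 0, mirna_fraction_threshold < 1,
            target_fraction > 0, target_fraction <= 1,
            nperm >= 1, is.numeric(seed), length(seed) == 1L)
  structure(as.list(environment()), class = "sponge_config")
}

#' Run the full sponge-scoring pipeline
#'
#' Stages: load (if `bundle` is a path list) -> miRNA sufficiency filter ->
#' collapse sites -> calibrate and apply the affinity cutoff -> rescale
#' affinities -> normalise MRE counts -> binomial MRE enrichment ->
#' expression scores -> sponge prerequisites -> SG (TOPSIS) -> S_EnrichSG
#' (preranked GSEA) -> SS (TOPSIS) -> ranked 16-column score matrix.
#' Deterministic given identical inputs and seed.
#'
#' @param bundle a `sponge_bundle` (e.g. from [generate_fixture()]) or a
#'   named path list for [load_input_bundle()].
#' @param config a [sponge_config()].
#' @return list of class `sponge_result`: `score_matrix`, `sg`, `enrich_sg`,
#'   `eligible`, `filter`, `cutoff`, `stage_counts`, `config`.
#' @export
run_pipeline <- function(bundle, config = sponge_config()) {
  if (!inherits(bundle, "sponge_bundle")) bundle <- load_input_bundle(bundle)
  counts <- list()

  mirna_data <- if (is.null(bundle$signature)) bundle$mirna_expr else bundle$signature
  kept <- filter_mirnas(mirna_data,
                        fraction_threshold = config$mirna_fraction_threshold,
                        exclude_zeros = config$q1_excludes_zeros)
  if (length(kept$kept_mirnas) == 0L) {
    sponge_abort("miRNA sufficiency filter removed every miRNA", "empty_result_error")
  }
  counts$mirnas_kept <- length(kept$kept_mirnas)

  circ_pairs <- collapse_sites(bundle$circ_sites)
  mrna_pairs <- collapse_sites(bundle$mrna_sites)
  counts$circ_pairs_collapsed <- nrow(circ_pairs)
  counts$mrna_pairs_collapsed <- nrow(mrna_pairs)

  cutoff <- NULL
  if (!is.null(bundle$validated)) {
    cutoff <- calibrate_affinity_cutoff(circ_pairs, bundle$validated,
                                        percentile = config$affinity_percentile,
                                        min_clip = config$min_clip,
                                        min_degradome = config$min_degradome)
    circ_pairs <- apply_affinity_cutoff(circ_pairs, cutoff)
    if (isTRUE(config$mrna_cutoff)) {
      mrna_pairs <- apply_affinity_cutoff(mrna_pairs, cutoff)
    }
  }
  counts$circ_pairs_after_cutoff <- nrow(circ_pairs)
  if (nrow(circ_pairs) == 0L) {
    sponge_abort("affinity cutoff removed every miRNA-circRNA pair", "empty_result_error")
  }

  circ_pairs <- rescale_affinity(circ_pairs)
  mrna_pairs <- rescale_affinity(mrna_pairs)
  circ_pairs <- normalize_mre_counts(circ_pairs, bundle$circ_lengths)
  mrna_pairs <- normalize_mre_counts(mrna_pairs)

  enr <- test_mre_enrichment(circ_pairs, alpha = config$enrichmre_alpha)
  circ_pairs <- enr$filtered
  counts$circ_pairs_after_enrichmre <- nrow(circ_pairs)
  if (nrow(circ_pairs) == 0L) {
    sponge_abort("MRE-enrichment filter removed every miRNA-circRNA pair",
                 "empty_result_error")
  }

  fc_circ <- compute_fold_change(bundle$circ_expr, bundle$annotation)
  fc_mrna <- compute_fold_change(bundle$mrna_expr, bundle$annotation)
  mirexpr <- compute_mirna_expression_score(mirna_data)
  te_circ <- compute_target_expression_score(bundle$circ_expr, bundle$annotation)
  te_mrna <- compute_target_expression_score(bundle$mrna_expr, bundle$annotation)
  directions <- split_by_direction(c(fc_circ, fc_mrna))

  eligible <- apply_sponge_prerequisites(circ_pairs, mrna_pairs, kept, directions)
  counts$eligible_pairs <- nrow(eligible)
  if (nrow(eligible) == 0L) {
    sponge_abort("sponge prerequisites removed every miRNA-circRNA pair",
                 "empty_result_error")
  }

  sg <- compute_sg(mrna_pairs, fc_mrna, mirexpr, te_mrna, eligible,
                   weights = config$weights_sg, abs_fc = config$abs_fc)
  enrich_sg <- compute_enrich_sg(sg, nperm = config$nperm, seed = config$seed,
                                 exact_limit = config$gsea_exact_limit)
  rows <- compute_sponge_scores(circ_pairs, fc_circ, mirexpr, te_circ,
                                enrich_sg, eligible, sg,
                                weights = config$weights_ss,
                                abs_fc = config$abs_fc,
                                neglog_costs = config$neglog_costs)
  score_matrix <- assemble_score_matrix(rows)
  counts$final_rows <- nrow(score_matrix)
  counts$condition_1 <- sum(score_matrix$condition == "condition_1")
  counts$condition_2 <- sum(score_matrix$condition == "condition_2")
  sponge_log("score matrix: %d mechanisms (%d condition_1 + %d condition_2)",
             counts$final_rows, counts$condition_1, counts$condition_2)

  structure(list(score_matrix = score_matrix, sg = sg, enrich_sg = enrich_sg,
                 eligible = eligible, filter = kept, cutoff = cutoff,
                 stage_counts = counts, config = config),
            class = "sponge_result")
}

#' @export
print.sponge_result <- function(x, ...) {
  cat(sprintf("<sponge result: %d ranked mechanisms (%d condition_1, %d condition_2)>\n",
              x$stage_counts$final_rows, x$stage_counts$condition_1,
              x$stage_counts$condition_2))
  invisible(x)
}
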
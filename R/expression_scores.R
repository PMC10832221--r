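# Expression-level criteria. Inputs are log2-scale, so fold changes are
# plain differences of condition means.

#' Log2 fold change per feature
#'
#' @param expr [expression_matrix()].
#' @param annotation [sample_annotation()]; all annotated samples must be
#'   present in the matrix.
#' @return named numeric vector: mean(condition_2) - mean(condition_1).
#' @export
compute_fold_change <- function(expr, annotation) {
  s1 <- annotation_samples(annotation, "condition_1")
  s2 <- annotation_samples(annotation, "condition_2")
  absent <- setdiff(c(s1, s2), colnames(expr))
  if (length(absent)) {
    sponge_abort(sprintf("annotation sample(s) missing from expression matrix: %s",
                         paste(absent, collapse = ", ")),
                 "shape_error")
  }
  rowMeans(expr[, s2, drop = FALSE]) - rowMeans(expr[, s1, drop = FALSE])
}

#' miRNA expression score (S_MirExpr)
#'
#' Median expression of each miRNA over all samples, both conditions pooled.
#' For a signature, the signature values are used verbatim (a note is logged:
#' cross-dataset comparability is the user's responsibility).
#'
#' @param mirna_expr miRNA [expression_matrix()] or [mirna_signature()].
#' @return named numeric vector.
#' @export
compute_mirna_expression_score <- function(mirna_expr) {
  if (inherits(mirna_expr, "sponge_signature")) {
    sponge_log("using signature '%s' values verbatim for S_MirExpr",
               attr(mirna_expr, "label"))
    return(stats::setNames(as.numeric(mirna_expr), names(mirna_expr)))
  }
  apply(mirna_expr, 1L, stats::median)
}

#' Target expression score (S_TargetExpr)
#'
#' The larger of the two per-condition mean log2 expressions of each feature.
#'
#' @inheritParams compute_fold_change
#' @return named numeric vector.
#' @export
compute_target_expression_score <- function(expr, annotation) {
  s1 <- annotation_samples(annotation, "condition_1")
  s2 <- annotation_samples(annotation, "condition_2")
  pmax(rowMeans(expr[, s1, drop = FALSE]), rowMeans(expr[, s2, drop = FALSE]))
}
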
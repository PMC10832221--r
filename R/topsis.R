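#' TOPSIS multi-criteria closeness scores
#'
#' Technique for Order of Preference by Similarity to Ideal Solution
#' (Hwang-Yoon). Steps: vector-normalise each criterion column
#' (x / sqrt(sum(x^2)); an all-zero column stays zero), multiply by weights,
#' form the ideal point (per-column max for benefit criteria, min for cost)
#' and the anti-ideal (the reverse), take Euclidean distances d+ and d- to
#' each, and return the closeness C = d- / (d+ + d-). When d+ + d- = 0
#' (a single alternative, or all rows identical) C = 0.5 by convention.
#'
#' @param values numeric matrix, alternatives in rows, criteria in columns.
#' @param directions character vector, `"benefit"` or `"cost"` per column.
#' @param weights positive weights, one per column; normalised to sum to 1.
#'   Default equal weights.
#' @return numeric vector of closeness values in [0, 1], named by rownames.
#' @export
topsis <- function(values, directions, weights = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) sponge_abort("no alternatives to score", "empty_input_error")
  if (any(!is.finite(values))) sponge_abort("decision matrix contains non-finite values", "shape_error")
  p <- ncol(values)
  if (length(directions) != p || !all(directions %in% c("benefit", "cost"))) {
    sponge_abort("directions must be 'benefit'/'cost', one per criterion", "shape_error")
  }
  if (is.null(weights)) weights <- rep(1, p)
  if (length(weights) != p || any(!is.finite(weights)) || any(weights <= 0)) {
    sponge_abort("weights must be positive and finite, one per criterion", "weight_error")
  }
  weights <- weights / sum(weights)

  norms <- sqrt(colSums(values^2))
  norms[norms == 0] <- 1                      # all-zero column -> stays zero
  v <- sweep(sweep(values, 2L, norms, "/"), 2L, weights, "*")

  benefit <- directions == "benefit"
  col_max <- apply(v, 2L, max)
  col_min <- apply(v, 2L, min)
  ideal <- ifelse(benefit, col_max, col_min)
  anti <- ifelse(benefit, col_min, col_max)

  d_pos <- sqrt(rowSums(sweep(v, 2L, ideal, "-")^2))
  d_neg <- sqrt(rowSums(sweep(v, 2L, anti, "-")^2))
  tot <- d_pos + d_neg
  closeness <- ifelse(tot == 0, 0.5, d_neg / tot)
  stats::setNames(as.numeric(closeness), rownames(values))
}
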
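#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix (features in rows, samples
#' in columns) carrying a `rna_type` attribute. Values are assumed to be
#' normalised, log2-scale expression; no transformation is applied here.
#'
#' Identifier conventions are enforced per RNA type: circRNAs must look like
#' circBase accessions (`hsa_circ_` + 7 digits), miRNAs must start with
#' `hsa-miR-` or `hsa-let-`, and mRNAs must be non-empty gene symbols. The
#' legacy misspelling `has_circ_` is auto-corrected with a warning.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param rna_type one of `"circRNA"`, `"mRNA"`, `"miRNA"`.
#' @param source optional file name used in error messages.
#' @return the validated matrix, class `sponge_expr`, with attribute
#'   `rna_type`.
#' @export
expression_matrix <- function(values, rna_type = c("circRNA", "mRNA", "miRNA"),
                              source = "<matrix>") {
  rna_type <- match.arg(rna_type)
  if (!is.matrix(values) || !is.numeric(values)) {
    sponge_abort(sprintf("%s: expression values must form a numeric matrix", source),
                 "shape_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    sponge_abort(sprintf("%s: expression matrix needs feature rownames and sample colnames", source),
                 "shape_error")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    sponge_abort(sprintf("%s: duplicate feature id '%s'", source, dup), "shape_error")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    sponge_abort(sprintf("%s: duplicate sample id '%s'", source, dup), "shape_error")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    sponge_abort(sprintf("%s: non-finite value at feature '%s', sample '%s'",
                         source, rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
                 "shape_error")
  }
  rownames(values) <- check_feature_ids(rownames(values), rna_type, source)
  structure(values, rna_type = rna_type, class = c("sponge_expr", class(values)))
}

#' @export
print.sponge_expr <- function(x, ...) {
  cat(sprintf("<%s expression matrix: %d features x %d samples>\n",
              attr(x, "rna_type"), nrow(x), ncol(x)))
  invisible(x)
}

check_feature_ids <- function(ids, rna_type, source) {
  if (any(!nzchar(ids) | is.na(ids))) {
    sponge_abort(sprintf("%s: empty feature identifier at row %d",
                         source, which(!nzchar(ids) | is.na(ids))[1L]),
                 "identifier_error")
  }
  if (rna_type == "circRNA") {
    typo <- grepl("^has_circ_[0-9]{7}$", ids)
    if (any(typo)) {
      sponge_warn(sprintf("%s: %d identifier(s) use the 'has_circ_' misspelling; auto-corrected to 'hsa_circ_'",
                          source, sum(typo)))
      ids[typo] <- sub("^has_", "hsa_", ids[typo])
    }
    bad <- !grepl("^hsa_circ_[0-9]{7}$", ids)
    if (any(bad)) {
      sponge_abort(sprintf("%s: malformed circRNA id '%s' (row %d); expected hsa_circ_ + 7 digits",
                           source, ids[bad][1L], which(bad)[1L]),
                   "identifier_error")
    }
  } else if (rna_type == "miRNA") {
    bad <- !grepl("^hsa-(miR|let)-", ids)
    if (any(bad)) {
      sponge_abort(sprintf("%s: malformed miRNA id '%s' (row %d); expected hsa-miR-* or hsa-let-*",
                           source, ids[bad][1L], which(bad)[1L]),
                   "identifier_error")
    }
  }
  ids
}

#' Construct a sample annotation
#'
#' Maps each sample to one of two conditions. `condition_1` is the control
#' condition. At least 3 samples per condition are required.
#'
#' @param sample_ids character vector of sample ids.
#' @param conditions character vector, values `condition_1` / `condition_2`.
#' @param source optional file name for error messages.
#' @return data.frame with columns `sample_id`, `condition`, class
#'   `sponge_annotation`.
#' @export
sample_annotation <- function(sample_ids, conditions, source = "<annotation>") {
  sample_ids <- as.character(sample_ids)
  conditions <- as.character(conditions)
  if (length(sample_ids) != length(conditions)) {
    sponge_abort(sprintf("%s: samples and conditions differ in length", source), "shape_error")
  }
  if (anyDuplicated(sample_ids)) {
    sponge_abort(sprintf("%s: duplicate sample id '%s'",
                         source, sample_ids[duplicated(sample_ids)][1L]),
                 "shape_error")
  }
  bad <- !conditions %in% c("condition_1", "condition_2")
  if (any(bad)) {
    sponge_abort(sprintf("%s: unknown condition label '%s' for sample '%s'",
                         source, conditions[bad][1L], sample_ids[bad][1L]),
                 "shape_error")
  }
  for (cond in c("condition_1", "condition_2")) {
    n <- sum(conditions == cond)
    if (n < 3L) {
      sponge_abort(sprintf("%s: %s has %d sample(s); a minimum of 3 samples per condition is required",
                           source, cond, n),
                   "sample_count_error")
    }
  }
  structure(data.frame(sample_id = sample_ids, condition = conditions,
                       stringsAsFactors = FALSE),
            class = c("sponge_annotation", "data.frame"))
}

annotation_samples <- function(annotation, condition = NULL) {
  if (is.null(condition)) return(annotation$sample_id)
  annotation$sample_id[annotation$condition == condition]
}

#' Construct a binding-site table
#'
#' One row per predicted miRNA recognition element (MRE). `score` is the raw
#' predicted context score: by TargetScan convention lower (more negative)
#' means stronger predicted repression.
#'
#' @param mirna_id,target_id,score,site vectors of equal length; `site` is a
#'   1-based site index making (mirna, target, site) unique.
#' @param target_type `"circRNA"` or `"mRNA"`, homogeneous for the table.
#' @param source optional file name for error messages.
#' @return data.frame with class `sponge_sites`.
#' @export
site_table <- function(mirna_id, target_id, score, site = NULL,
                       target_type = c("circRNA", "mRNA"), source = "<sites>") {
  target_type <- match.arg(target_type)
  n <- length(mirna_id)
  if (is.null(site)) site <- stats::ave(seq_len(n), mirna_id, target_id, FUN = seq_along)
  df <- data.frame(mirna_id = as.character(mirna_id),
                   target_id = as.character(target_id),
                   target_type = target_type,
                   score = as.numeric(score),
                   site = as.integer(site),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$score))) {
    sponge_abort(sprintf("%s: non-numeric site score at row %d",
                         source, which(!is.finite(df$score))[1L]),
                 "shape_error")
  }
  if (any(df$site < 1L)) {
    sponge_abort(sprintf("%s: site index < 1 at row %d", source, which(df$site < 1L)[1L]),
                 "shape_error")
  }
  key <- paste(df$mirna_id, df$target_id, df$site, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    sponge_abort(sprintf("%s: duplicate site (%s, %s, site %d) at row %d",
                         source, df$mirna_id[i], df$target_id[i], df$site[i], i),
                 "shape_error")
  }
  df$mirna_id <- check_feature_ids(df$mirna_id, "miRNA", source)
  df$target_id <- check_feature_ids(df$target_id, target_type, source)
  df <- df[order(df$mirna_id, df$target_id, df$site), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("sponge_sites", "data.frame"))
}

#' Construct a circRNA spliced-length table
#'
#' @param circ_id character vector of circRNA ids.
#' @param length_nt strictly positive integer spliced lengths (nucleotides).
#' @param source optional file name for error messages.
#' @return named integer vector.
#' @export
circ_length_table <- function(circ_id, length_nt, source = "<lengths>") {
  circ_id <- check_feature_ids(as.character(circ_id), "circRNA", source)
  length_nt <- as.numeric(length_nt)
  if (any(!is.finite(length_nt) | length_nt <= 0)) {
    i <- which(!is.finite(length_nt) | length_nt <= 0)[1L]
    sponge_abort(sprintf("%s: non-positive spliced length for '%s'", source, circ_id[i]),
                 "shape_error")
  }
  if (anyDuplicated(circ_id)) {
    sponge_abort(sprintf("%s: duplicate circRNA id '%s'",
                         source, circ_id[duplicated(circ_id)][1L]),
                 "shape_error")
  }
  stats::setNames(as.integer(round(length_nt)), circ_id)
}

#' Construct a validated-interaction table
#'
#' Experimentally supported (miRNA, circRNA) interactions with CLIP-seq and
#' degradome-seq evidence counts, used to calibrate the affinity cutoff.
#'
#' @param mirna_id,circ_id,n_clipseq,n_degradome equal-length vectors.
#' @param source optional file name for error messages.
#' @return data.frame with class `sponge_validated`.
#' @export
validated_table <- function(mirna_id, circ_id, n_clipseq, n_degradome,
                            source = "<validated>") {
  df <- data.frame(mirna_id = check_feature_ids(as.character(mirna_id), "miRNA", source),
                   circ_id = check_feature_ids(as.character(circ_id), "circRNA", source),
                   n_clipseq = as.integer(n_clipseq),
                   n_degradome = as.integer(n_degradome),
                   stringsAsFactors = FALSE)
  if (any(df$n_clipseq < 0L | df$n_degradome < 0L)) {
    sponge_abort(sprintf("%s: negative evidence count", source), "shape_error")
  }
  key <- paste(df$mirna_id, df$circ_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    sponge_abort(sprintf("%s: duplicate validated pair (%s, %s)",
                         source, df$mirna_id[i], df$circ_id[i]),
                 "shape_error")
  }
  structure(df, class = c("sponge_validated", "data.frame"))
}

#' Construct a miRNA expression signature
#'
#' A named vector of log2-scale expression values standing in for a missing
#' miRNA expression matrix (e.g. a cancer-type signature). Signatures are
#' assumed to be pre-filtered for sufficiently expressed miRNAs, so the Q1
#' sufficiency filter is skipped when a signature is used.
#'
#' @param values named numeric vector (miRNA id -> log2 expression).
#' @param label signature name.
#' @param source optional file name for error messages.
#' @return named numeric vector with attribute `label`, class
#'   `sponge_signature`.
#' @export
mirna_signature <- function(values, label = "signature", source = "<signature>") {
  if (length(values) == 0L) {
    sponge_abort(sprintf("%s: empty miRNA signature", source), "shape_error")
  }
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    sponge_abort(sprintf("%s: signature values must be named by miRNA id", source),
                 "shape_error")
  }
  if (any(!is.finite(values))) {
    sponge_abort(sprintf("%s: non-finite signature value for '%s'",
                         source, names(values)[!is.finite(values)][1L]),
                 "shape_error")
  }
  names(values) <- check_feature_ids(names(values), "miRNA", source)
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), label = label,
            class = "sponge_signature")
}
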
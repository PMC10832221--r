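# All inputs are plain CSV (comma-separated, UTF-8, '.' decimal, header row).
# Expression files: first column = feature id, remaining columns = samples.

read_csv_strict <- function(path) {
  if (!file.exists(path)) {
    sponge_abort(sprintf("file not found: %s", path), "io_error")
  }
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an expression matrix from CSV
#'
#' @param path CSV file; first column holds feature identifiers, remaining
#'   columns one sample each.
#' @param rna_type `"circRNA"`, `"mRNA"` or `"miRNA"`.
#' @return a validated [expression_matrix()].
#' @export
read_expression_matrix <- function(path, rna_type) {
  df <- read_csv_strict(path)
  if (ncol(df) < 2L) {
    sponge_abort(sprintf("%s: expression file needs a feature column plus sample columns", path),
                 "shape_error")
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (any(is.na(v) & !is.na(vals[[j]]))) {
      i <- which(is.na(v) & !is.na(vals[[j]]))[1L]
      sponge_abort(sprintf("%s: non-numeric cell '%s' at row %d (feature '%s'), column '%s'",
                           path, vals[[j]][i], i, ids[i], names(vals)[j]),
                   "shape_error")
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, rna_type, source = path)
}

#' Read a sample annotation from CSV
#'
#' The file must contain columns `samples` and `conditions`; conditions are
#' `condition_1` (control) and `condition_2`, each with at least 3 samples.
#'
#' @param path CSV file path.
#' @return a [sample_annotation()].
#' @export
read_sample_annotation <- function(path) {
  df <- read_csv_strict(path)
  for (col in c("samples", "conditions")) {
    if (!col %in% names(df)) {
      sponge_abort(sprintf("%s: annotation is missing required column '%s'", path, col),
                   "missing_column_error")
    }
  }
  sample_annotation(df$samples, df$conditions, source = path)
}

#' Read a binding-site table from CSV
#'
#' Expected columns: `mirna`, `target`, `score`, optionally `site` (1-based
#' site index) and `target_type`.
#'
#' @param path CSV file path.
#' @param target_type `"circRNA"` or `"mRNA"`; must match any `target_type`
#'   column present in the file.
#' @return a [site_table()].
#' @export
read_site_table <- function(path, target_type) {
  df <- read_csv_strict(path)
  for (col in c("mirna", "target", "score")) {
    if (!col %in% names(df)) {
      sponge_abort(sprintf("%s: site table is missing required column '%s'", path, col),
                   "missing_column_error")
    }
  }
  if ("target_type" %in% names(df) && any(df$target_type != target_type)) {
    sponge_abort(sprintf("%s: mixed or unexpected target_type values (expected '%s')",
                         path, target_type),
                 "shape_error")
  }
  site <- if ("site" %in% names(df)) df$site else NULL
  site_table(df$mirna, df$target, df$score, site = site,
             target_type = target_type, source = path)
}

#' Read a circRNA spliced-length table from CSV
#'
#' First column = circRNA id, second column = spliced length in nucleotides.
#'
#' @param path CSV file path.
#' @return named integer vector of lengths.
#' @export
read_circ_lengths <- function(path) {
  df <- read_csv_strict(path)
  if (ncol(df) < 2L) {
    sponge_abort(sprintf("%s: length table needs id and length columns", path), "shape_error")
  }
  circ_length_table(df[[1L]], df[[2L]], source = path)
}

#' Read a validated-interaction table from CSV
#'
#' Expected columns: `mirna`, `circ`, `n_clipseq`, `n_degradome`.
#'
#' @param path CSV file path.
#' @return a [validated_table()].
#' @export
read_validated_table <- function(path) {
  df <- read_csv_strict(path)
  for (col in c("mirna", "circ", "n_clipseq", "n_degradome")) {
    if (!col %in% names(df)) {
      sponge_abort(sprintf("%s: validated table is missing required column '%s'", path, col),
                   "missing_column_error")
    }
  }
  validated_table(df$mirna, df$circ, df$n_clipseq, df$n_degradome, source = path)
}

#' Read a miRNA signature from CSV
#'
#' First column = miRNA id, second column = log2-scale expression value.
#'
#' @param path CSV file path.
#' @param label signature name; defaults to the file name.
#' @return a [mirna_signature()].
#' @export
read_mirna_signature <- function(path, label = basename(path)) {
  df <- read_csv_strict(path)
  if (ncol(df) < 2L) {
    sponge_abort(sprintf("%s: signature needs id and value columns", path), "shape_error")
  }
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  mirna_signature(stats::setNames(vals, as.character(df[[1L]])), label = label,
                  source = path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Gene symbols are uppercased and deduplicated within each set.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene sets), with attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) sponge_abort(sprintf("file not found: %s", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      sponge_abort(sprintf("%s: line %d has %d field(s); GMT requires name, description and >= 1 gene",
                           path, i, length(fields)),
                   "format_error")
    }
    name <- fields[1L]
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      sponge_abort(sprintf("%s: line %d (set '%s') has no genes", path, i, name),
                   "format_error")
    }
    sets[[name]] <- genes
    desc[[name]] <- fields[2L]
  }
  structure(sets, descriptions = desc)
}

score_matrix_columns <- c(
  "mirna_id", "circ_id", "s_affinity", "s_nbmre", "s_enrichmre",
  "s_fc_circ", "s_mirexpr", "s_targetexpr_circ", "s_enrichsg", "ss",
  "rank_global", "condition", "rank_in_condition", "n_mrna_targets",
  "mean_sg_of_targets", "mrna_target_list")

#' Write the 16-column score matrix to CSV
#'
#' Rows are written sorted by global rank (ascending). The file round-trips
#' losslessly through [read_score_matrix()].
#'
#' @param matrix score matrix as produced by [assemble_score_matrix()].
#' @param path output CSV path.
#' @export
write_score_matrix <- function(matrix, path) {
  missing <- setdiff(score_matrix_columns, names(matrix))
  if (length(missing)) {
    sponge_abort(sprintf("score matrix lacks column(s): %s", paste(missing, collapse = ", ")),
                 "shape_error")
  }
  out <- as.data.frame(matrix)[, score_matrix_columns, drop = FALSE]
  if (nrow(out) == 0L) {
    sponge_warn(sprintf("writing empty score matrix to %s", path))
  } else {
    out <- out[order(out$rank_global), , drop = FALSE]
  }
  num <- vapply(out, is.numeric, logical(1L)) & !vapply(out, is.integer, logical(1L))
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#'
#' @param path CSV file path.
#' @return data.frame with the 16 documented columns.
#' @export
read_score_matrix <- function(path) {
  df <- read_csv_strict(path)
  missing <- setdiff(score_matrix_columns, names(df))
  if (length(missing)) {
    sponge_abort(sprintf("%s: score matrix lacks column(s): %s",
                         path, paste(missing, collapse = ", ")),
                 "shape_error")
  }
  int_cols <- c("rank_global", "rank_in_condition", "n_mrna_targets")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  chr_cols <- c("mirna_id", "circ_id", "condition", "mrna_target_list")
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  num_cols <- setdiff(score_matrix_columns, c(int_cols, chr_cols))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df[, score_matrix_columns, drop = FALSE]
}

#' Load and cross-validate a complete input bundle
#'
#' Reads every input file, enforces identifier conventions and the 3-samples
#' rule, and resolves cross-references: site-table rows whose target lacks an
#' expression row, or whose miRNA is absent from the miRNA data, are dropped
#' with a logged count.
#'
#' @param paths named list of file paths with elements `circ_expr`,
#'   `mrna_expr`, `annotation`, `circ_sites`, `mrna_sites`, `circ_lengths`,
#'   and either `mirna_expr` or `signature`; optional `validated` and
#'   `mirna_annotation` (annotation for a miRNA matrix with its own samples).
#' @return a list of class `sponge_bundle`.
#' @export
load_input_bundle <- function(paths) {
  required <- c("circ_expr", "mrna_expr", "annotation", "circ_sites",
                "mrna_sites", "circ_lengths")
  missing <- setdiff(required, names(paths))
  if (length(missing)) {
    sponge_abort(sprintf("input bundle lacks path(s): %s", paste(missing, collapse = ", ")),
                 "io_error")
  }
  if (is.null(paths$mirna_expr) && is.null(paths$signature)) {
    sponge_abort("either a miRNA expression matrix or a miRNA signature is required",
                 "io_error")
  }
  circ_expr <- read_expression_matrix(paths$circ_expr, "circRNA")
  mrna_expr <- read_expression_matrix(paths$mrna_expr, "mRNA")
  annotation <- read_sample_annotation(paths$annotation)

  mirna_expr <- NULL
  signature <- NULL
  mirna_annotation <- NULL
  if (!is.null(paths$mirna_expr)) {
    mirna_expr <- read_expression_matrix(paths$mirna_expr, "miRNA")
    mirna_annotation <- if (!is.null(paths$mirna_annotation)) {
      read_sample_annotation(paths$mirna_annotation)
    } else {
      # sample pairing across RNA types is not required; reuse the main
      # annotation when the miRNA matrix shares its samples
      if (all(annotation$sample_id %in% colnames(mirna_expr))) annotation else NULL
    }
  } else {
    signature <- read_mirna_signature(paths$signature)
  }

  for (nm in c("circ_expr", "mrna_expr")) {
    m <- get(nm)
    absent <- setdiff(annotation$sample_id, colnames(m))
    if (length(absent)) {
      sponge_abort(sprintf("%s: annotation sample(s) missing from %s matrix: %s",
                           paths[[nm]], attr(m, "rna_type"), paste(absent, collapse = ", ")),
                   "shape_error")
    }
  }

  circ_sites <- read_site_table(paths$circ_sites, "circRNA")
  mrna_sites <- read_site_table(paths$mrna_sites, "mRNA")
  circ_lengths <- read_circ_lengths(paths$circ_lengths)
  validated <- if (!is.null(paths$validated)) read_validated_table(paths$validated) else NULL

  mirna_universe <- if (is.null(signature)) rownames(mirna_expr) else names(signature)
  circ_sites <- drop_unresolved_sites(circ_sites, rownames(circ_expr), mirna_universe,
                                      "circRNA site table")
  mrna_sites <- drop_unresolved_sites(mrna_sites, rownames(mrna_expr), mirna_universe,
                                      "mRNA site table")

  sponge_log("loaded bundle: %d circRNAs, %d mRNAs, %d miRNAs, %d samples (%d + %d)",
             nrow(circ_expr), nrow(mrna_expr), length(mirna_universe),
             nrow(annotation),
             sum(annotation$condition == "condition_1"),
             sum(annotation$condition == "condition_2"))

  structure(list(circ_expr = circ_expr, mrna_expr = mrna_expr,
                 mirna_expr = mirna_expr, signature = signature,
                 annotation = annotation, mirna_annotation = mirna_annotation,
                 circ_sites = circ_sites, mrna_sites = mrna_sites,
                 circ_lengths = circ_lengths, validated = validated),
            class = "sponge_bundle")
}

drop_unresolved_sites <- function(sites, target_universe, mirna_universe, what) {
  keep <- sites$target_id %in% target_universe & sites$mirna_id %in% mirna_universe
  if (any(!keep)) {
    sponge_log("%s: dropped %d site(s) without matching expression rows", what, sum(!keep))
    sites <- sites[keep, , drop = FALSE]
    rownames(sites) <- NULL
  }
  sites
}

#' @export
print.sponge_bundle <- function(x, ...) {
  cat(sprintf("<sponge input bundle: %d circRNAs, %d mRNAs, %s, %d annotated samples>\n",
              nrow(x$circ_expr), nrow(x$mrna_expr),
              if (is.null(x$signature)) sprintf("%d miRNAs", nrow(x$mirna_expr))
              else sprintf("signature '%s' (%d miRNAs)", attr(x$signature, "label"),
                           length(x$signature)),
              nrow(x$annotation)))
  invisible(x)
}
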
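# Star subnetworks around a selected interaction or RNA, their file export,
# and a local gene-set over-representation test.

#' Build a circRNA-miRNA-mRNA star subnetwork
#'
#' The selection is either a (miRNA, circRNA) pair or a single RNA id
#' matching any score-matrix row. Each matching row contributes its
#' circRNA-miRNA edge weighted by SS, and the miRNA's co-directional mRNA
#' targets ranked by SG, truncated to `ceiling(target_fraction * count)`
#' nodes (minimum 1), with edges weighted by SG. Focus nodes are drawn
#' larger than the rest.
#'
#' @param matrix score matrix from [assemble_score_matrix()].
#' @param sg SG table from [compute_sg()].
#' @param mirna,circ select one interaction; or use `rna` to select every
#'   row mentioning one RNA id.
#' @param rna single RNA id (circRNA or miRNA) selecting all its rows.
#' @param target_fraction fraction of ranked mRNA targets to keep
#'   (default 0.10).
#' @param literature optional data.frame (`mirna_id`, `circ_id`) of known
#'   mechanisms; matching circRNA edges are flagged `in_literature`.
#' @return list of class `sponge_network` with `nodes` and `edges`
#'   data.frames.
#' @export
build_subnetwork <- function(matrix, sg, mirna = NULL, circ = NULL, rna = NULL,
                             target_fraction = 0.10, literature = NULL) {
  if (!is.null(rna)) {
    rows <- matrix[matrix$mirna_id == rna | matrix$circ_id == rna, , drop = FALSE]
    focus <- rna
  } else if (!is.null(mirna) && !is.null(circ)) {
    rows <- matrix[matrix$mirna_id == mirna & matrix$circ_id == circ, , drop = FALSE]
    focus <- c(mirna, circ)
  } else {
    sponge_abort("select either rna = <id> or mirna = + circ =", "not_found_error")
  }
  if (nrow(rows) == 0L) {
    sponge_abort("selection matches no score-matrix row", "not_found_error")
  }

  lit_key <- if (is.null(literature)) character(0) else {
    paste(literature$mirna_id, literature$circ_id, sep = "\r")
  }

  nodes <- list()
  edges <- list()
  add_node <- function(id, type) {
    if (is.null(nodes[[id]])) nodes[[id]] <<- list(id = id, rna_type = type)
  }
  for (i in seq_len(nrow(rows))) {
    m <- rows$mirna_id[i]
    c_ <- rows$circ_id[i]
    add_node(m, "miRNA")
    add_node(c_, "circRNA")
    edges[[length(edges) + 1L]] <- list(
      source = m, target = c_, kind = "miRNA-circRNA",
      weight = rows$ss[i],
      in_literature = paste(m, c_, sep = "\r") %in% lit_key)
    targets <- strsplit(rows$mrna_target_list[i], ";", fixed = TRUE)[[1L]]
    sub <- sg[sg$mirna_id == m & sg$mrna_id %in% targets, , drop = FALSE]
    sub <- sub[order(-sub$sg, sub$mrna_id), , drop = FALSE]
    n_keep <- max(1L, ceiling(target_fraction * nrow(sub)))
    sub <- sub[seq_len(min(n_keep, nrow(sub))), , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      add_node(sub$mrna_id[j], "mRNA")
      edges[[length(edges) + 1L]] <- list(
        source = m, target = sub$mrna_id[j], kind = "miRNA-mRNA",
        weight = sub$sg[j], in_literature = FALSE)
    }
  }
  nodes_df <- do.call(rbind, lapply(nodes, function(n) {
    data.frame(id = n$id, rna_type = n$rna_type, stringsAsFactors = FALSE)
  }))
  rownames(nodes_df) <- NULL
  nodes_df$is_focus <- nodes_df$id %in% focus
  nodes_df$display_size <- ifelse(nodes_df$is_focus, 2, 1)
  edges_df <- do.call(rbind, lapply(edges, function(e) {
    data.frame(source = e$source, target = e$target, kind = e$kind,
               weight = e$weight, in_literature = e$in_literature,
               stringsAsFactors = FALSE)
  }))
  edges_df <- unique(edges_df)
  rownames(edges_df) <- NULL
  structure(list(nodes = nodes_df, edges = edges_df), class = "sponge_network")
}

#' @export
print.sponge_network <- function(x, ...) {
  cat(sprintf("<sponge network: %d nodes (%s), %d edges>\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$rna_type),
                            names(table(x$nodes$rna_type))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Export a sponge network to GraphML or JSON
#'
#' Attributes (`rna_type`, `is_focus`, `display_size` on nodes; `kind`,
#' `weight`, `in_literature` on edges) are preserved; JSON files re-import
#' losslessly via [import_network()].
#'
#' @param net a `sponge_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @export
export_network <- function(net, path, format = c("graphml", "json")) {
  if (!is.character(format) || !all(format %in% c("graphml", "json"))) {
    sponge_abort("unsupported network format; supported formats: graphml, json",
                 "format_error")
  }
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = net$nodes, edges = net$edges), path,
                         auto_unbox = FALSE, digits = NA)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("source", "target", "kind", "weight", "in_literature")],
      directed = FALSE, vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a JSON network written by [export_network()]
#'
#' @param path JSON file path.
#' @return a `sponge_network`.
#' @export
import_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(nodes = as.data.frame(obj$nodes), edges = as.data.frame(obj$edges)),
            class = "sponge_network")
}

#' Hypergeometric over-representation of gene sets
#'
#' Local stand-in for a web enrichment service: for each gene set (clipped to
#' the background) the one-sided upper-tail hypergeometric p-value of its
#' overlap with the query is computed; BH adjustment across sets; rows are
#' returned sorted by p-value.
#'
#' @param query_genes character vector; must be a subset of `background`.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame: `set_name`, `overlap_count`, `set_size`, `query_size`,
#'   `background_size`, `pvalue`, `adjusted_pvalue`.
#' @export
ora_enrichment <- function(query_genes, collection, background) {
  query_genes <- unique(toupper(query_genes))
  background <- unique(toupper(background))
  if (length(query_genes) == 0L) sponge_abort("empty query gene set", "empty_query_error")
  outside <- setdiff(query_genes, background)
  if (length(outside)) {
    sponge_abort(sprintf("query gene(s) outside the background: %s",
                         paste(utils::head(outside, 5L), collapse = ", ")),
                 "empty_query_error")
  }
  Nb <- length(background)
  q <- length(query_genes)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(toupper(collection[[nm]]), background)
    k <- length(intersect(set, query_genes))
    s <- length(set)
    # P(overlap >= k) with q draws from Nb containing s set genes
    p <- stats::phyper(k - 1L, s, Nb - s, q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, set_size = s,
               query_size = q, background_size = Nb, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_pvalue <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
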
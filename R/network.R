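#' Thresholded correlation network of a gene set at a timepoint
#'
#' Builds the undirected network whose nodes are the requested genes
#' (each annotated with its sample SD at the timepoint) and whose edges
#' connect pairs with `|PCC| > threshold` (weak edges, `|PCC| <=
#' threshold`, are deleted). Constant genes get SD 0 and no edges.
#'
#' @param genes Character vector of >= 2 gene ids.
#' @param raw Expression matrix (log2 scale).
#' @param meta Sample metadata.
#' @param t Timepoint (`timepoint_order`) with >= 3 non-control samples.
#' @param threshold Absolute-correlation cutoff (default 0.4; strict
#'   `>`).
#' @return A `correlation_network` list: `timepoint`, `threshold`,
#'   `nodes` (data frame `gene`, `sd`) and `edges` (data frame `from`,
#'   `to`, `weight` with `from < to`).
#' @export
correlation_network <- function(genes, raw, meta, t, threshold = 0.4) {
  s <- samples_at(meta, t)
  if (length(s) < 3L) stop("correlation_network: fewer than 3 samples at timepoint ", t)
  if (length(genes) < 2L) stop("correlation_network: need >= 2 genes")
  stopifnot(threshold >= 0)
  x <- raw[genes, s, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  cm <- suppressWarnings(stats::cor(t(x)))
  idx <- which(upper.tri(cm) & !is.na(cm) & abs(cm) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = genes[idx[, 1L]], to = genes[idx[, 2L]],
    weight = cm[idx], stringsAsFactors = FALSE)
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    timepoint = t, threshold = threshold,
    nodes = data.frame(gene = genes, sd = unname(sdv),
                       stringsAsFactors = FALSE),
    edges = edges), class = "correlation_network")
}

#' Edge counts of a gene set's correlation network over timepoints
#'
#' @inheritParams correlation_network
#' @param timepoints Vector of `timepoint_order` values.
#' @return Data frame with `timepoint` and `n_edges`.
#' @export
edge_count_trajectory <- function(genes, raw, meta, timepoints,
                                  threshold = 0.4) {
  counts <- vapply(timepoints, function(t) {
    nrow(correlation_network(genes, raw, meta, t, threshold)$edges)
  }, integer(1L))
  data.frame(timepoint = timepoints, n_edges = counts)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-detail-style TSV with columns `protein1`, `protein2`
#' and `combined_score`, normalizes 0-1000 integer scores to `[0, 1]`,
#' and keeps edges at or above the confidence threshold.
#'
#' @param path Path to the TSV (whitespace- or tab-delimited).
#' @param score_threshold Minimum normalized combined score (default
#'   0.7; comparison is `>=`).
#' @return Data frame `protein1`, `protein2`, `score` (normalized). An
#'   empty file yields zero rows.
#' @export
load_ppi_edges <- function(path, score_threshold = 0.7) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(protein1 = character(0), protein2 = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("protein1", "protein2", "combined_score")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols)) {
    stop("PPI file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  score <- as.numeric(df$combined_score)
  if (length(score) && max(score, na.rm = TRUE) > 1) score <- score / 1000
  keep <- !is.na(score) & score >= score_threshold
  out <- data.frame(protein1 = as.character(df$protein1[keep]),
                    protein2 = as.character(df$protein2[keep]),
                    score = score[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export a correlation network to GraphML or an edge list
#'
#' GraphML (via igraph) carries node `sd` attributes and edge weights in
#' one file. The `edgelist` format writes a whitespace edge table and a
#' companion `<path>.nodes.tsv` with the node SD attributes, so a round
#' trip through either format recovers the full network.
#'
#' @param net A `correlation_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @seealso [import_network()]
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(net, "correlation_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = net$nodes$gene, sd = net$nodes$sd,
                            stringsAsFactors = FALSE))
    igraph::graph_attr(g, "timepoint") <- net$timepoint
    igraph::graph_attr(g, "threshold") <- net$threshold
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a correlation network written by [export_network()]
#'
#' @param path Path given to [export_network()].
#' @param format `"graphml"` or `"edgelist"`.
#' @return A `correlation_network` (the `timepoint`/`threshold` fields
#'   are recovered from GraphML; for edge lists they are `NA`).
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(gene = igraph::V(g)$name, sd = igraph::V(g)$sd,
                        stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(from = el$from, to = el$to, weight = el$weight,
                        stringsAsFactors = FALSE)
    tp <- igraph::graph_attr(g, "timepoint")
    th <- igraph::graph_attr(g, "threshold")
  } else {
    edges <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    nodes <- utils::read.table(paste0(path, ".nodes.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    tp <- NA_integer_
    th <- NA_real_
  }
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  structure(list(timepoint = tp, threshold = th, nodes = nodes,
                 edges = edges), class = "correlation_network")
}
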
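#' @title Network topology metrics
#' @description Degree and betweenness centrality for the network view, the
#'   standard first look at hub structure after simplifying a pathway.
#'   All edges are treated as undirected and the graph is simplified
#'   (parallel edges count once, loops dropped) before computing; scores
#'   are unnormalized by default, with equal splitting among equal-length
#'   shortest paths and endpoints excluded, each unordered pair counted
#'   once.
#' @name topology
NULL

#' Degree and betweenness of every node
#'
#' @param graph A [network_graph()].
#' @param normalize Divide betweenness by `(n-1)(n-2)/2`? Default `FALSE`
#'   (raw counts).
#' @return Data frame with columns `node_id`, `degree` (integer) and
#'   `betweenness` (double), one row per node, in node insertion order.
#' @export
centrality_table <- function(graph, normalize = FALSE) {
  stopifnot(inherits(graph, "network_graph"))
  ids <- ng_node_ids(graph)
  if (length(ids) == 0)
    return(data.frame(node_id = character(0), degree = integer(0),
                      betweenness = numeric(0), stringsAsFactors = FALSE))
  ig <- .ng_as_igraph(graph, simplify = TRUE)
  deg <- igraph::degree(ig, mode = "all", loops = FALSE)
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = isTRUE(normalize))
  ord <- match(ids, igraph::V(ig)$name)
  data.frame(node_id = ids, degree = as.integer(deg[ord]),
             betweenness = as.numeric(btw[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree of every node
#'
#' Undirected degree on the simplified graph (a collapsed parallel edge
#' counts once).
#'
#' @param graph A [network_graph()].
#' @return Named integer vector, node id to degree.
#' @export
node_degree <- function(graph) {
  ct <- centrality_table(graph)
  stats::setNames(ct$degree, ct$node_id)
}

#' Betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness on the undirected simple graph
#' (endpoints excluded; each unordered pair counted once; equal split over
#' equally short paths).
#'
#' @param graph A [network_graph()].
#' @param normalize See [centrality_table()].
#' @return Named numeric vector, node id to betweenness.
#' @export
node_betweenness <- function(graph, normalize = FALSE) {
  ct <- centrality_table(graph, normalize = normalize)
  stats::setNames(ct$betweenness, ct$node_id)
}

#' Write a centrality table as TSV
#' @param centrality A data frame from [centrality_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(centrality, path) {
  utils::write.table(centrality, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
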
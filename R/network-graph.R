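#' @title View-independent network graph container
#' @description Both converters emit a `network_graph`: typed nodes
#'   (kinds: `molecule`, `group`, `connector`, `annotation`) and typed,
#'   optionally directed edges, each carrying a free-form attribute list.
#'   Node ids are unique; every edge endpoint must exist; a node's kind is
#'   fixed at creation.
#' @name network-graph
NULL

.NODE_KINDS <- c("molecule", "group", "connector", "annotation")

#' Create an empty network graph
#' @return An object of class `network_graph` with empty node and edge sets.
#' @export
network_graph <- function() {
  structure(list(nodes = list(), edges = list(), meta = list()),
            class = "network_graph")
}

#' Add a node to a network graph
#' @param graph A [network_graph()].
#' @param node_id Unique node id.
#' @param kind One of `"molecule"`, `"group"`, `"connector"`, `"annotation"`.
#' @param attributes Named list of node attributes.
#' @return The updated graph.
#' @export
ng_add_node <- function(graph, node_id, kind, attributes = list()) {
  stopifnot(inherits(graph, "network_graph"))
  kind <- match.arg(kind, .NODE_KINDS)
  node_id <- as.character(node_id)
  if (node_id %in% names(graph$nodes))
    stop("node id '", node_id, "' already exists", call. = FALSE)
  graph$nodes[[node_id]] <- list(node_id = node_id, kind = kind, attributes = attributes)
  graph
}

#' Add an edge to a network graph
#' @param graph A [network_graph()].
#' @param edge_id Unique edge id.
#' @param source,target Existing node ids.
#' @param interaction_type Free-form relation type (arrow-head name,
#'   `"contains"`, `"undirected"` ...).
#' @param directed Logical; whether the edge is directed source to target.
#' @param attributes Named list of edge attributes.
#' @return The updated graph.
#' @export
ng_add_edge <- function(graph, edge_id, source, target,
                        interaction_type = "undirected", directed = TRUE,
                        attributes = list()) {
  stopifnot(inherits(graph, "network_graph"))
  edge_id <- as.character(edge_id)
  if (edge_id %in% names(graph$edges))
    stop("edge id '", edge_id, "' already exists", call. = FALSE)
  for (ep in c(source, target))
    if (!ep %in% names(graph$nodes))
      stop("edge '", edge_id, "' endpoint '", ep, "' is not a node", call. = FALSE)
  graph$edges[[edge_id]] <- list(edge_id = edge_id, source = as.character(source),
                                 target = as.character(target),
                                 interaction_type = as.character(interaction_type),
                                 directed = isTRUE(directed), attributes = attributes)
  graph
}

#' Node ids of a graph
#' @param graph A [network_graph()].
#' @return Character vector of node ids in insertion order.
#' @export
ng_node_ids <- function(graph) names(graph$nodes)

#' Edge ids of a graph
#' @param graph A [network_graph()].
#' @return Character vector of edge ids in insertion order.
#' @export
ng_edge_ids <- function(graph) names(graph$edges)

#' Node table of a graph
#' @param graph A [network_graph()].
#' @return Data frame with columns `node_id` and `kind`.
#' @export
ng_nodes <- function(graph) {
  data.frame(node_id = names(graph$nodes),
             kind = vapply(graph$nodes, `[[`, "", "kind"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge table of a graph
#' @param graph A [network_graph()].
#' @return Data frame with columns `edge_id`, `source`, `target`,
#'   `interaction_type`, `directed`.
#' @export
ng_edges <- function(graph) {
  if (length(graph$edges) == 0)
    return(data.frame(edge_id = character(0), source = character(0),
                      target = character(0), interaction_type = character(0),
                      directed = logical(0), stringsAsFactors = FALSE))
  data.frame(edge_id = names(graph$edges),
             source = vapply(graph$edges, `[[`, "", "source"),
             target = vapply(graph$edges, `[[`, "", "target"),
             interaction_type = vapply(graph$edges, `[[`, "", "interaction_type"),
             directed = vapply(graph$edges, `[[`, TRUE, "directed"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Get one node attribute
#' @param graph A [network_graph()].
#' @param node_id Node id.
#' @param name Attribute name.
#' @return The attribute value, or `NULL` when absent.
#' @export
ng_node_attr <- function(graph, node_id, name) {
  n <- graph$nodes[[node_id]]
  if (is.null(n)) stop("no node '", node_id, "'", call. = FALSE)
  n$attributes[[name]]
}

#' Set node attributes
#' @param graph A [network_graph()].
#' @param node_id Node id.
#' @param ... Named attribute values.
#' @return The updated graph.
#' @export
ng_set_node_attr <- function(graph, node_id, ...) {
  if (!node_id %in% names(graph$nodes))
    stop("no node '", node_id, "'", call. = FALSE)
  vals <- list(...)
  for (nm in names(vals)) graph$nodes[[node_id]]$attributes[[nm]] <- vals[[nm]]
  graph
}

#' @export
print.network_graph <- function(x, ...) {
  kinds <- table(factor(vapply(x$nodes, `[[`, "", "kind"), levels = .NODE_KINDS))
  cat(sprintf("network_graph: %d nodes, %d edges\n", length(x$nodes), length(x$edges)))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

# Convert to an igraph object (undirected simple graph when simplify = TRUE).
# Multiplicities introduced by collapsing are ignored: a collapsed edge
# counts once, matching the documented degree semantics.
.ng_as_igraph <- function(graph, simplify = TRUE) {
  ids <- names(graph$nodes)
  ed <- ng_edges(graph)
  g <- igraph::graph_from_data_frame(
    if (nrow(ed) == 0) data.frame(from = character(0), to = character(0))
    else data.frame(from = ed$source, to = ed$target, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (simplify) g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g
}
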
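#' @title Simplified network view
#' @description Converts a pathway document into an analysis-ready network:
#'   graphical annotations (labels, shapes, graphical lines) are removed,
#'   redundant data nodes are merged into one unique molecule node, groups
#'   and anchors are kept as very small nodes, and a seeded force-directed
#'   layout provides coordinates. The whole conversion is deterministic
#'   from the document and the options.
#' @name view-network
NULL

#' Options controlling the network-view conversion
#'
#' @param collapse_parallel_edges Collapse edges with identical (source,
#'   target, interaction type) into one edge carrying a `multiplicity`
#'   attribute. Default `TRUE`.
#' @param drop_dangling_edges Drop interaction edges whose endpoint does not
#'   resolve (with a warning). Default `TRUE`.
#' @param layout_seed Seed for the force-directed layout. Default 42.
#' @param layout_iterations Layout iteration count, at least 1. Default 100.
#' @return An object of class `network_options`.
#' @export
network_options <- function(collapse_parallel_edges = TRUE,
                            drop_dangling_edges = TRUE,
                            layout_seed = 42L, layout_iterations = 100L) {
  stopifnot(layout_iterations >= 1)
  structure(list(collapse_parallel_edges = isTRUE(collapse_parallel_edges),
                 drop_dangling_edges = isTRUE(drop_dangling_edges),
                 layout_seed = as.integer(layout_seed),
                 layout_iterations = as.integer(layout_iterations)),
            class = "network_options")
}

#' Merge key of a data node
#'
#' Two data nodes are redundant — and merge into one network node — when
#' they share a non-empty cross-reference; nodes without a usable xref fall
#' back to their (entity type, case-sensitive label) pair.
#'
#' @param node A [gpml_data_node()].
#' @return A single string key, `"xref|<datasource>|<identifier>"` or
#'   `"label|<entity_type>|<text_label>"`.
#' @export
merge_key <- function(node) {
  stopifnot(inherits(node, "gpml_data_node"))
  if (nzchar(node$xref$datasource) && nzchar(node$xref$identifier))
    paste("xref", node$xref$datasource, node$xref$identifier, sep = "|")
  else
    paste("label", node$entity_type, node$text_label, sep = "|")
}

#' Report which data nodes merge together
#'
#' @param doc A [pathway_document()].
#' @return A named list: merge key to character vector of the graph ids of
#'   the contributing data nodes (document order). The vectors partition
#'   the set of all data-node ids.
#' @export
merge_report <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  rep <- list()
  for (dn in doc$data_nodes) {
    k <- merge_key(dn)
    rep[[k]] <- c(rep[[k]], dn$graph_id)
  }
  rep
}

#' Seeded force-directed layout
#'
#' Runs the Fruchterman–Reingold algorithm with a fixed seed and iteration
#' count; repeated calls with the same inputs give identical coordinates.
#' A single node is placed at the origin. If the layout leaves two nodes
#' exactly coincident, a deterministic nudge separates them.
#'
#' @param graph A nonempty [network_graph()].
#' @param seed Integer RNG seed.
#' @param iterations Number of layout iterations.
#' @return Data frame with columns `node_id`, `x`, `y`.
#' @export
apply_layout <- function(graph, seed = 42L, iterations = 100L) {
  stopifnot(inherits(graph, "network_graph"))
  ids <- ng_node_ids(graph)
  if (length(ids) == 0) stop("cannot lay out an empty graph", call. = FALSE)
  if (length(ids) == 1)
    return(data.frame(node_id = ids, x = 0, y = 0, stringsAsFactors = FALSE))

  ig <- .ng_as_igraph(graph, simplify = TRUE)
  xy <- withr::with_seed(as.integer(seed),
    igraph::layout_with_fr(ig, niter = as.integer(iterations)))
  out <- data.frame(node_id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE)
  out <- out[match(ids, out$node_id), , drop = FALSE]
  rownames(out) <- NULL

  # separate exact coincidences deterministically (rare; degenerate inputs)
  key <- paste(out$x, out$y)
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    out$x[i] <- out$x[i] + 1e-3 * i
    out$y[i] <- out$y[i] + 1e-3 * i
    key <- paste(out$x, out$y)
  }
  out
}

#' Convert a pathway document to the simplified network view
#'
#' Labels, shapes and graphical lines contribute nothing. Data nodes are
#' merged by [merge_key()]; a merged node keeps the first contributor (in
#' document order) as its representative and records all source graph ids.
#' Each group becomes one small group node joined to its members by
#' undirected `"contains"` edges; each anchor on a used interaction becomes
#' a small connector node splitting the interaction's edge. Coordinates
#' come from [apply_layout()] under `opts$layout_seed`.
#'
#' @param doc A valid [pathway_document()].
#' @param opts A [network_options()].
#' @return A list with components `graph` (a [network_graph()]), `styles`
#'   (a `style_table` holding positions and the small group/connector
#'   sizes) and `merge` (the [merge_report()]).
#' @export
to_network_view <- function(doc, opts = network_options()) {
  .stop_if_invalid(doc)
  stopifnot(inherits(opts, "network_options"))

  rep <- merge_report(doc)
  dn_by_id <- stats::setNames(doc$data_nodes,
                              vapply(doc$data_nodes, `[[`, "", "graph_id"))

  g <- network_graph()
  buf <- style_buffer()

  # merged molecule nodes: id = representative graph id (first in doc order)
  id_of_source <- list()  # original graph_id -> merged node id
  for (k in names(rep)) {
    ids <- rep[[k]]
    repr <- dn_by_id[[ids[1]]]
    all_identifiers <- unique(vapply(ids, function(i) dn_by_id[[i]]$xref$identifier, ""))
    g <- ng_add_node(g, repr$graph_id, "molecule", attributes = list(
      text_label = repr$text_label, entity_type = repr$entity_type,
      xref_datasource = repr$xref$datasource, xref_identifier = repr$xref$identifier,
      merge_key = k, merged_ids = paste(ids, collapse = ","),
      n_merged = length(ids),
      all_identifiers = paste(all_identifiers[nzchar(all_identifiers)], collapse = ",")))
    for (i in ids) id_of_source[[i]] <- repr$graph_id
  }

  # group nodes and membership edges
  for (gr in doc$groups) {
    nid <- .group_node_id(gr)
    g <- ng_add_node(g, nid, "group",
                     attributes = list(group_id = gr$group_id, group_style = gr$style))
    members <- .group_members(doc, gr$group_id)
    seen <- character(0)
    for (m in members) {
      tgt <- id_of_source[[m$graph_id]]
      if (is.null(tgt) || tgt %in% seen) next
      seen <- c(seen, tgt)
      g <- ng_add_edge(g, sprintf("contains:%s:%s", gr$group_id, tgt), nid, tgt,
                       interaction_type = "contains", directed = FALSE)
    }
  }

  # resolve an interaction endpoint to its network node id
  refmap_doc <- .ref_to_node_map(doc)
  anchors_present <- character(0)
  for (ia in doc$interactions)
    anchors_present <- c(anchors_present, vapply(ia$anchors, `[[`, "", "graph_id"))
  resolve_net <- function(ref) {
    if (is.null(ref) || !nzchar(ref)) return(NULL)
    if (!is.null(id_of_source[[ref]])) return(id_of_source[[ref]])
    if (ref %in% anchors_present) return(ref)  # connector node, created below
    el <- resolve_ref(doc, ref)
    if (inherits(el, "gpml_group")) return(.group_node_id(el))
    NULL  # labels, shapes, graphical-line anchors: annotation targets dropped
  }

  # connector nodes for anchors on biological interactions
  for (ia in doc$interactions) {
    for (a in ia$anchors)
      g <- ng_add_node(g, a$graph_id, "connector",
                       attributes = list(parent_line = ia$graph_id,
                                         position = a$position))
  }

  # interaction edges, split at anchors
  pending <- list()
  for (ia in doc$interactions) {
    pts <- ia$points
    src <- resolve_net(pts[[1]]$graph_ref)
    tgt <- resolve_net(pts[[length(pts)]]$graph_ref)
    itype <- .line_interaction_type(ia)
    if (is.null(src) || is.null(tgt)) {
      if (is.null(src) && is.null(tgt)) {
        warning("interaction '", ia$graph_id, "': both endpoints dangling; dropped",
                call. = FALSE)
        next
      }
      if (opts$drop_dangling_edges) {
        warning("interaction '", ia$graph_id, "': dangling endpoint; edge dropped",
                call. = FALSE)
        next
      }
      # keep with a placeholder connector standing in for the missing end
      ph <- sprintf("dangling:%s", ia$graph_id)
      g <- ng_add_node(g, ph, "connector", attributes = list(placeholder = TRUE))
      if (is.null(src)) src <- ph else tgt <- ph
    }
    anchors <- ia$anchors
    if (length(anchors) > 1)
      anchors <- anchors[order(vapply(anchors, `[[`, 0, "position"))]
    chain <- c(src, vapply(anchors, `[[`, "", "graph_id"), tgt)
    n_seg <- length(chain) - 1L
    for (i in seq_len(n_seg)) {
      eid <- if (n_seg == 1L) ia$graph_id else sprintf("%s:%d", ia$graph_id, i)
      etype <- if (i == n_seg) itype else "segment"
      pending[[length(pending) + 1L]] <- list(
        edge_id = eid, source = chain[i], target = chain[i + 1L],
        interaction_type = etype, directed = !identical(itype, "undirected"),
        attributes = list(parent_line = ia$graph_id))
    }
  }

  if (opts$collapse_parallel_edges) {
    seen_key <- character(0)
    kept <- list()
    for (e in pending) {
      k <- paste(e$source, e$target, e$interaction_type, sep = "\r")
      j <- match(k, seen_key)
      if (is.na(j)) {
        e$attributes$multiplicity <- 1L
        kept[[length(kept) + 1L]] <- e
        seen_key <- c(seen_key, k)
      } else {
        kept[[j]]$attributes$multiplicity <- kept[[j]]$attributes$multiplicity + 1L
      }
    }
    pending <- kept
  }
  for (e in pending)
    g <- ng_add_edge(g, e$edge_id, e$source, e$target, e$interaction_type,
                     e$directed, e$attributes)

  # styles: "very small" group/connector nodes, molecule defaults, layout
  for (id in ng_node_ids(g)) {
    kind <- g$nodes[[id]]$kind
    if (kind %in% c("group", "connector")) {
      buf <- record_style(buf, id, "width", 5.0)
      buf <- record_style(buf, id, "height", 5.0)
      buf <- record_style(buf, id, "fill_color", "808080")
      buf <- record_style(buf, id, "shape", "Ellipse")
    } else {
      buf <- record_style(buf, id, "width", 60.0)
      buf <- record_style(buf, id, "height", 25.0)
      buf <- record_style(buf, id, "fill_color", "FFFFFF")
      buf <- record_style(buf, id, "border_color", "000000")
      lbl <- ng_node_attr(g, id, "text_label")
      if (!is.null(lbl)) buf <- record_style(buf, id, "label", lbl)
    }
  }
  if (length(ng_node_ids(g)) > 0) {
    coords <- apply_layout(g, opts$layout_seed, opts$layout_iterations)
    for (i in seq_len(nrow(coords))) {
      buf <- record_style(buf, coords$node_id[i], "x", coords$x[i])
      buf <- record_style(buf, coords$node_id[i], "y", coords$y[i])
    }
  }

  list(graph = g, styles = apply_styles(g, buf), merge = rep)
}
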
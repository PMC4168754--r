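#' @title Annotated pathway view
#' @description Converts a pathway document into a graph whose layout and
#'   appearance replicate the drawn diagram: every data node, label, shape,
#'   group and anchor becomes a node, every interaction and graphical line
#'   contributes edges, and node positions in the style table equal the
#'   GPML center coordinates exactly. Nothing is dropped.
#' @name view-pathway
NULL

# map every referencable id (graph ids, group ids, anchor ids) to the node id
# used in the converted graph
.ref_to_node_map <- function(doc) {
  m <- list()
  for (dn in doc$data_nodes) m[[dn$graph_id]] <- dn$graph_id
  for (lb in doc$labels) m[[lb$graph_id]] <- lb$graph_id
  for (sh in doc$shapes) m[[sh$graph_id]] <- sh$graph_id
  for (coll in c("interactions", "graphical_lines"))
    for (ia in doc[[coll]])
      for (a in ia$anchors) m[[a$graph_id]] <- a$graph_id
  for (gr in doc$groups) {
    nid <- if (!is.null(gr$graph_id)) gr$graph_id else gr$group_id
    m[[gr$group_id]] <- nid
    if (!is.null(gr$graph_id)) m[[gr$graph_id]] <- nid
  }
  m
}

.group_node_id <- function(gr) if (!is.null(gr$graph_id)) gr$graph_id else gr$group_id

# members of a group: data nodes, labels, shapes with matching group_ref
.group_members <- function(doc, group_id) {
  out <- list()
  for (dn in doc$data_nodes)
    if (identical(dn$group_ref, group_id)) out <- c(out, list(dn))
  out
}

# bounding-box center and extent of a group's members; GPML stores no group
# coordinates of its own
.group_bbox <- function(doc, gr) {
  members <- .group_members(doc, gr$group_id)
  if (length(members) == 0)
    return(list(x = 0, y = 0, w = 10, h = 10))
  xs_lo <- vapply(members, function(m) m$graphics$center_x - m$graphics$width / 2, 0)
  xs_hi <- vapply(members, function(m) m$graphics$center_x + m$graphics$width / 2, 0)
  ys_lo <- vapply(members, function(m) m$graphics$center_y - m$graphics$height / 2, 0)
  ys_hi <- vapply(members, function(m) m$graphics$center_y + m$graphics$height / 2, 0)
  list(x = (min(xs_lo) + max(xs_hi)) / 2, y = (min(ys_lo) + max(ys_hi)) / 2,
       w = max(xs_hi) - min(xs_lo), h = max(ys_hi) - min(ys_lo))
}

# coordinate of an anchor: linear interpolation at its position fraction
# along the straight segment between the line's first and last point
.anchor_xy <- function(line, anchor) {
  p1 <- line$points[[1]]
  p2 <- line$points[[length(line$points)]]
  list(x = p1$x + anchor$position * (p2$x - p1$x),
       y = p1$y + anchor$position * (p2$y - p1$y))
}

.record_gfx_styles <- function(buf, id, g) {
  buf <- record_style(buf, id, "x", g$center_x)
  buf <- record_style(buf, id, "y", g$center_y)
  buf <- record_style(buf, id, "width", g$width)
  buf <- record_style(buf, id, "height", g$height)
  buf <- record_style(buf, id, "fill_color", g$fill_color)
  buf <- record_style(buf, id, "border_color", g$border_color)
  buf <- record_style(buf, id, "shape", g$shape_name)
  buf <- record_style(buf, id, "z_order", g$z_order)
  buf
}

# add the edges contributed by one interaction / graphical line.
# With anchors present the main edge is split into a chain
# source -> anchor_1 -> ... -> anchor_k -> target (anchors ordered by
# position); edges attached to an anchor simply target the anchor node.
.add_line_edges <- function(graph, buf, line, refmap, interaction_type,
                            directed, extra_attrs = list(),
                            on_dangling = c("skip", "drop_flagged")) {
  on_dangling <- match.arg(on_dangling)
  pts <- line$points
  src_ref <- pts[[1]]$graph_ref
  tgt_ref <- pts[[length(pts)]]$graph_ref
  src <- if (!is.null(src_ref)) refmap[[src_ref]] else NULL
  tgt <- if (!is.null(tgt_ref)) refmap[[tgt_ref]] else NULL
  if (is.null(src) || is.null(tgt)) {
    warning("line '", line$graph_id, "' has a dangling endpoint; edge skipped",
            call. = FALSE)
    return(list(graph = graph, buf = buf))
  }
  anchors <- line$anchors
  if (length(anchors) > 1)
    anchors <- anchors[order(vapply(anchors, `[[`, 0, "position"))]
  chain <- c(src, vapply(anchors, `[[`, "", "graph_id"), tgt)
  n_seg <- length(chain) - 1L
  for (i in seq_len(n_seg)) {
    eid <- if (n_seg == 1L) line$graph_id else sprintf("%s:%d", line$graph_id, i)
    # only the final segment carries the arrow head
    etype <- if (i == n_seg) interaction_type else "segment"
    graph <- ng_add_edge(graph, eid, chain[i], chain[i + 1L],
                         interaction_type = etype, directed = directed,
                         attributes = c(list(parent_line = line$graph_id), extra_attrs))
    buf <- record_style(buf, eid, "line_style", line$graphics$line_style,
                        target_class = "edge")
    if (i == n_seg && !identical(interaction_type, "undirected"))
      buf <- record_style(buf, eid, "arrow_shape", interaction_type,
                          target_class = "edge")
  }
  list(graph = graph, buf = buf)
}

.line_interaction_type <- function(line) {
  ah <- line$points[[length(line$points)]]$arrow_head
  if (is.null(ah) || !nzchar(ah) || identical(ah, "none")) "undirected" else ah
}

#' Convert a pathway document to the annotated pathway view
#'
#' Every data node (kind `molecule`), label and shape (kind `annotation`),
#' group (kind `group`) and anchor (kind `connector`) becomes a node.
#' Interactions contribute directed edges (split at anchors); graphical
#' lines contribute undirected edges flagged `graphical = TRUE`. The style
#' table carries x/y positions equal to the GPML center coordinates
#' bit-for-bit, plus extent, colors, labels and shapes, so the diagram
#' layout is reproduced exactly.
#'
#' @param doc A valid [pathway_document()].
#' @return A list with components `graph` (a [network_graph()]) and
#'   `styles` (a resolved `style_table`).
#' @export
to_pathway_view <- function(doc) {
  .stop_if_invalid(doc)
  refmap <- .ref_to_node_map(doc)
  g <- network_graph()
  buf <- style_buffer()

  for (dn in doc$data_nodes) {
    g <- ng_add_node(g, dn$graph_id, "molecule", attributes = list(
      text_label = dn$text_label, entity_type = dn$entity_type,
      xref_datasource = dn$xref$datasource, xref_identifier = dn$xref$identifier,
      group_ref = dn$group_ref,
      states = if (length(dn$states) > 0)
        paste(vapply(dn$states, `[[`, "", "text_label"), collapse = ";") else NULL))
    buf <- .record_gfx_styles(buf, dn$graph_id, dn$graphics)
    buf <- record_style(buf, dn$graph_id, "label", dn$text_label)
  }
  for (lb in doc$labels) {
    g <- ng_add_node(g, lb$graph_id, "annotation",
                     attributes = list(text_label = lb$text_label, element = "Label"))
    buf <- .record_gfx_styles(buf, lb$graph_id, lb$graphics)
    buf <- record_style(buf, lb$graph_id, "label", lb$text_label)
  }
  for (sh in doc$shapes) {
    g <- ng_add_node(g, sh$graph_id, "annotation", attributes = list(element = "Shape"))
    buf <- .record_gfx_styles(buf, sh$graph_id, sh$graphics)
  }
  for (gr in doc$groups) {
    nid <- .group_node_id(gr)
    g <- ng_add_node(g, nid, "group",
                     attributes = list(group_id = gr$group_id, group_style = gr$style))
    bb <- .group_bbox(doc, gr)
    buf <- record_style(buf, nid, "x", bb$x)
    buf <- record_style(buf, nid, "y", bb$y)
    buf <- record_style(buf, nid, "width", bb$w)
    buf <- record_style(buf, nid, "height", bb$h)
    buf <- record_style(buf, nid, "fill_color", "EEEEEE")
    buf <- record_style(buf, nid, "border_color", "808080")
  }
  for (coll in c("interactions", "graphical_lines")) {
    for (ia in doc[[coll]]) {
      for (a in ia$anchors) {
        xy <- .anchor_xy(ia, a)
        g <- ng_add_node(g, a$graph_id, "connector",
                         attributes = list(parent_line = ia$graph_id,
                                           position = a$position))
        buf <- record_style(buf, a$graph_id, "x", xy$x)
        buf <- record_style(buf, a$graph_id, "y", xy$y)
        buf <- record_style(buf, a$graph_id, "width", 5.0)
        buf <- record_style(buf, a$graph_id, "height", 5.0)
        buf <- record_style(buf, a$graph_id, "fill_color", "000000")
        buf <- record_style(buf, a$graph_id, "shape", "Ellipse")
      }
    }
  }
  for (ia in doc$interactions) {
    res <- .add_line_edges(g, buf, ia, refmap, .line_interaction_type(ia),
                           directed = !identical(.line_interaction_type(ia), "undirected"))
    g <- res$graph; buf <- res$buf
  }
  for (gl in doc$graphical_lines) {
    res <- .add_line_edges(g, buf, gl, refmap, "undirected", directed = FALSE,
                           extra_attrs = list(graphical = TRUE))
    g <- res$graph; buf <- res$buf
  }

  list(graph = g, styles = apply_styles(g, buf))
}
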
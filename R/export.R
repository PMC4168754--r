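#' @title Graph exporters
#' @description Serializes a [network_graph()] (optionally with its style
#'   table) to GraphML, SIF and node-link JSON for downstream network
#'   tools. All exporters emit nodes and edges sorted by id, so identical
#'   inputs give byte-identical output; encoding is UTF-8 with LF line
#'   endings.
#' @name export
NULL

# GraphML attribute type of an R value
.graphml_type <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.integer(v)) "long"
  else if (is.numeric(v)) "double"
  else if (is.character(v)) "string"
  else NA_character_
}

.collect_attr_keys <- function(items, styles_for = NULL, styles = NULL) {
  keys <- list()
  for (it in items) {
    for (nm in names(it$attributes)) {
      v <- it$attributes[[nm]]
      if (is.null(v)) next
      ty <- .graphml_type(v)
      if (is.na(ty))
        stop("attribute '", nm, "' has unsupported type ", class(v)[1], call. = FALSE)
      if (is.null(keys[[nm]])) keys[[nm]] <- ty
      else if (keys[[nm]] != ty) keys[[nm]] <- "string"
    }
  }
  if (!is.null(styles) && nrow(styles) > 0) {
    props <- unique(styles$property[styles$target_class == styles_for])
    for (p in props) keys[[paste0("style_", p)]] <- "string"
  }
  if (length(keys) == 0) return(keys)
  keys[order(names(keys))]
}

.fmt_attr <- function(v) {
  if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) .fmt_num(v)
  else as.character(v)
}

#' Export a graph to GraphML
#'
#' Declares a typed key for every node/edge attribute in use; when a style
#' table is given, its properties are added as `style_<property>` string
#' attributes. The output re-parses (e.g. with a generic GraphML reader)
#' to exactly the same node and edge sets.
#'
#' @param graph A [network_graph()].
#' @param styles Optional `style_table`.
#' @return GraphML XML text.
#' @export
to_graphml <- function(graph, styles = NULL) {
  stopifnot(inherits(graph, "network_graph"))
  node_keys <- .collect_attr_keys(graph$nodes, "node", styles)
  node_keys <- c(list(kind = "string"), node_keys[names(node_keys) != "kind"])
  edge_keys <- .collect_attr_keys(graph$edges, "edge", styles)
  edge_keys <- c(list(interaction_type = "string", directed = "boolean"),
                 edge_keys[!names(edge_keys) %in% c("interaction_type", "directed")])

  x <- xml2::xml_new_root("graphml",
                          xmlns = "http://graphml.graphdrawing.org/xmlns")
  key_id <- function(domain, nm) paste0(substr(domain, 1, 1), "_", nm)
  for (nm in names(node_keys))
    .add_child(x, "key", list(id = key_id("node", nm), `for` = "node",
                              attr.name = nm, attr.type = node_keys[[nm]]))
  for (nm in names(edge_keys))
    .add_child(x, "key", list(id = key_id("edge", nm), `for` = "edge",
                              attr.name = nm, attr.type = edge_keys[[nm]]))
  gx <- .add_child(x, "graph", list(id = "G", edgedefault = "directed"))

  style_rows <- function(id, cls) {
    if (is.null(styles)) return(NULL)
    styles[styles$target_id == id & styles$target_class == cls, , drop = FALSE]
  }
  emit_data <- function(parent, domain, nm, value) {
    d <- .add_child(parent, "data", list(key = key_id(domain, nm)))
    xml2::xml_set_text(d, .fmt_attr(value))
  }

  for (id in sort(ng_node_ids(graph))) {
    n <- graph$nodes[[id]]
    el <- .add_child(gx, "node", list(id = id))
    emit_data(el, "node", "kind", n$kind)
    for (nm in setdiff(names(node_keys), "kind")) {
      v <- if (startsWith(nm, "style_")) NULL else n$attributes[[nm]]
      if (!is.null(v)) emit_data(el, "node", nm, v)
    }
    sr <- style_rows(id, "node")
    if (!is.null(sr) && nrow(sr) > 0)
      for (i in seq_len(nrow(sr)))
        emit_data(el, "node", paste0("style_", sr$property[i]), sr$value[i])
  }
  for (eid in sort(ng_edge_ids(graph))) {
    e <- graph$edges[[eid]]
    el <- .add_child(gx, "edge", list(id = eid, source = e$source, target = e$target))
    emit_data(el, "edge", "interaction_type", e$interaction_type)
    emit_data(el, "edge", "directed", e$directed)
    for (nm in setdiff(names(edge_keys), c("interaction_type", "directed"))) {
      v <- if (startsWith(nm, "style_")) NULL else e$attributes[[nm]]
      if (!is.null(v)) emit_data(el, "edge", nm, v)
    }
    sr <- style_rows(eid, "edge")
    if (!is.null(sr) && nrow(sr) > 0)
      for (i in seq_len(nrow(sr)))
        emit_data(el, "edge", paste0("style_", sr$property[i]), sr$value[i])
  }
  as.character(x)
}

#' Export a graph to SIF (Simple Interaction Format)
#'
#' One line per edge, `source<TAB>interaction_type<TAB>target`; isolated
#' nodes are emitted as single-token lines. Nodes and edges are sorted by
#' id, so the output is deterministic. SIF carries no attributes; use
#' [write_node_attributes_tsv()] for a sidecar table.
#'
#' @param graph A [network_graph()].
#' @return SIF text (possibly empty).
#' @export
to_sif <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  ed <- ng_edges(graph)
  lines <- character(0)
  if (nrow(ed) > 0) {
    ed <- ed[order(ed$edge_id), , drop = FALSE]
    lines <- sprintf("%s\t%s\t%s", ed$source, ed$interaction_type, ed$target)
  }
  connected <- unique(c(ed$source, ed$target))
  isolated <- sort(setdiff(ng_node_ids(graph), connected))
  lines <- c(lines, isolated)
  if (length(lines) == 0) return("")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write node attributes as a TSV sidecar for SIF
#'
#' @param graph A [network_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes_tsv <- function(graph, path) {
  ids <- sort(ng_node_ids(graph))
  keys <- sort(unique(unlist(lapply(graph$nodes, function(n) names(n$attributes)))))
  header <- c("node_id", "kind", keys)
  rows <- vapply(ids, function(id) {
    n <- graph$nodes[[id]]
    vals <- vapply(keys, function(k) {
      v <- n$attributes[[k]]
      if (is.null(v)) "" else .fmt_attr(v)
    }, "")
    paste(c(id, n$kind, vals), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Export a graph to node-link JSON
#'
#' Top-level `"nodes"` and `"edges"` arrays with attributes inline; when a
#' style table is given each element additionally carries its resolved
#' styles under a `"style"` key. The schema the output conforms to is
#' shipped at `system.file("extdata", "network-graph.schema.json",
#' package = "gpmlgraph")`.
#'
#' @param graph A [network_graph()].
#' @param styles Optional `style_table`.
#' @return JSON text.
#' @export
to_json_graph <- function(graph, styles = NULL) {
  stopifnot(inherits(graph, "network_graph"))
  style_obj <- function(id, cls) {
    if (is.null(styles)) return(NULL)
    sr <- styles[styles$target_id == id & styles$target_class == cls, , drop = FALSE]
    if (nrow(sr) == 0) return(NULL)
    stats::setNames(as.list(sr$value), sr$property)
  }
  nodes <- lapply(sort(ng_node_ids(graph)), function(id) {
    n <- graph$nodes[[id]]
    o <- c(list(id = id, kind = n$kind),
           n$attributes[!vapply(n$attributes, is.null, TRUE)])
    st <- style_obj(id, "node")
    if (!is.null(st)) o$style <- st
    o
  })
  edges <- lapply(sort(ng_edge_ids(graph)), function(eid) {
    e <- graph$edges[[eid]]
    o <- c(list(id = eid, source = e$source, target = e$target,
                interaction_type = e$interaction_type, directed = e$directed),
           e$attributes[!vapply(e$attributes, is.null, TRUE)])
    st <- style_obj(eid, "edge")
    if (!is.null(st)) o$style <- st
    o
  })
  jsonlite::toJSON(list(nodes = nodes, edges = edges),
                   auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
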
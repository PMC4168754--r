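#' @title Deferred visual styles
#' @description While a converter is still building a graph, the view
#'   objects that would receive visual properties do not exist yet. Style
#'   assignments are therefore recorded into a buffer during construction
#'   and resolved against the finished graph in a second pass; later
#'   assignments to the same (target, property) pair win. The resolved
#'   result is a `style_table`: at most one value per (target, property).
#' @name deferred-styles
NULL

.STYLE_PROPS <- c("fill_color", "border_color", "border_width", "width",
                  "height", "x", "y", "label", "shape", "line_style",
                  "arrow_shape", "z_order", "size")

#' Create an empty deferred-style buffer
#' @return A zero-row data frame with columns `target_id`, `target_class`,
#'   `property`, `value`.
#' @export
style_buffer <- function() {
  data.frame(target_id = character(0), target_class = character(0),
             property = character(0), value = character(0),
             stringsAsFactors = FALSE)
}

#' Record a deferred style assignment
#'
#' The target need not exist yet — that is the point of deferral; it must
#' exist when [apply_styles()] resolves the buffer.
#'
#' @param buf A [style_buffer()].
#' @param target_id Node or edge id the style applies to.
#' @param property Style property name (one of the documented vocabulary).
#' @param value Property value (stored as character).
#' @param target_class `"node"` or `"edge"`.
#' @return The buffer with the assignment appended.
#' @export
record_style <- function(buf, target_id, property, value, target_class = "node") {
  property <- match.arg(property, .STYLE_PROPS)
  target_class <- match.arg(target_class, c("node", "edge"))
  rbind(buf, data.frame(target_id = as.character(target_id),
                        target_class = target_class,
                        property = property, value = as.character(value),
                        stringsAsFactors = FALSE))
}

#' Resolve a deferred-style buffer against a finished graph
#'
#' Applies last-write-wins resolution and verifies that every target exists
#' in `graph`. The call is idempotent (same buffer, same table) and never
#' modifies the graph.
#'
#' @param graph The finished [network_graph()].
#' @param buf A buffer built with [record_style()].
#' @return A `style_table`: data frame `target_id`, `target_class`,
#'   `property`, `value` with at most one row per (target, property),
#'   ordered by target then property.
#' @export
apply_styles <- function(graph, buf) {
  stopifnot(inherits(graph, "network_graph"))
  if (nrow(buf) == 0) return(structure(style_buffer(), class = c("style_table", "data.frame")))

  is_node <- buf$target_class == "node"
  missing_nodes <- setdiff(unique(buf$target_id[is_node]), ng_node_ids(graph))
  missing_edges <- setdiff(unique(buf$target_id[!is_node]), ng_edge_ids(graph))
  if (length(missing_nodes) + length(missing_edges) > 0)
    stop("deferred style targets do not exist in the graph: ",
         paste(c(missing_nodes, missing_edges), collapse = ", "), call. = FALSE)

  # last write wins: keep the final occurrence of each (target, property)
  key <- paste(buf$target_id, buf$target_class, buf$property, sep = "\r")
  keep <- !duplicated(key, fromLast = TRUE)
  out <- buf[keep, , drop = FALSE]
  out <- out[order(out$target_class, out$target_id, out$property), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("style_table", "data.frame"))
}

#' Look up one resolved style value
#' @param styles A `style_table`.
#' @param target_id Target id.
#' @param property Property name.
#' @return The value as character, or `NA` when unset.
#' @export
style_value <- function(styles, target_id, property) {
  hit <- styles$target_id == target_id & styles$property == property
  if (!any(hit)) return(NA_character_)
  styles$value[which(hit)[1]]
}

#' Write a style table as TSV
#'
#' Columns: `target_id`, `target_class`, `property`, `value`.
#'
#' @param styles A `style_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_style_tsv <- function(styles, path) {
  utils::write.table(as.data.frame(styles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Serialize a style table to JSON
#'
#' One object per target: `{"<target_id>": {"class": ..., "<property>":
#' <value>, ...}}`.
#'
#' @param styles A `style_table`.
#' @return JSON text.
#' @export
style_to_json <- function(styles) {
  ids <- unique(styles$target_id)
  out <- lapply(ids, function(id) {
    rows <- styles[styles$target_id == id, , drop = FALSE]
    c(list(class = rows$target_class[1]),
      stats::setNames(as.list(rows$value), rows$property))
  })
  names(out) <- ids
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
}
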
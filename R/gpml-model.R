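#' @title GPML document model
#' @description Typed in-memory representation of the GPML 2013a subset the
#'   converters consume: data nodes, interactions with anchors, graphical
#'   lines, labels, shapes, groups and states. All coordinates are native
#'   board units with the origin at the top-left and y growing downward
#'   (the GPML convention); no rescaling is performed.
#' @name gpml-model
NULL

# Fixed table mapping GPML named colors to RRGGBB. GPML 2013a allows a small
# set of java.awt color names alongside hex values.
.GPML_NAMED_COLORS <- c(
  Black = "000000", White = "FFFFFF", Red = "FF0000", Green = "00FF00",
  Blue = "0000FF", Yellow = "FFFF00", Cyan = "00FFFF", Magenta = "FF00FF",
  Gray = "808080", Grey = "808080", LightGray = "C0C0C0",
  DarkGray = "404040", Orange = "FFC800", Pink = "FFAFAF", Transparent = "FFFFFF"
)

#' Normalize a GPML color to uppercase RRGGBB
#'
#' Accepts hex strings (with or without a leading `#`, case-insensitive) and
#' the GPML named colors; 8-digit AARRGGBB hex drops the alpha byte.
#'
#' @param x Color string.
#' @param default Fallback used when `x` is `NULL`, `NA` or empty.
#' @return Uppercase six-character hex string.
#' @export
normalize_color <- function(x, default = "000000") {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) return(default)
  x <- trimws(x)
  if (x %in% names(.GPML_NAMED_COLORS)) return(unname(.GPML_NAMED_COLORS[x]))
  x <- toupper(sub("^#", "", x))
  if (grepl("^[0-9A-F]{8}$", x)) x <- substr(x, 3L, 8L)  # drop alpha
  if (grepl("^[0-9A-F]{6}$", x)) return(x)
  default
}

#' Cross-reference (datasource + identifier)
#'
#' A database annotation of a pathway element, e.g. Entrez Gene 1017.
#' Fields may be empty but never carry leading/trailing whitespace;
#' equality is exact, case-sensitive pair equality.
#'
#' @param datasource Datasource name (e.g. `"Entrez Gene"`, `"Ensembl"`).
#' @param identifier Identifier within that datasource.
#' @return An object of class `gpml_xref`.
#' @export
gpml_xref <- function(datasource = "", identifier = "") {
  structure(list(datasource = trimws(as.character(datasource)[1]),
                 identifier = trimws(as.character(identifier)[1])),
            class = "gpml_xref")
}

#' Graphics properties of a drawable element
#'
#' @param center_x,center_y Center position in board units (y grows downward).
#' @param width,height Extent in board units; must be positive for drawable
#'   elements.
#' @param fill_color,border_color Hex RRGGBB colors (normalized uppercase).
#' @param shape_name GPML shape type string.
#' @param z_order Integer stacking order.
#' @param line_style `"solid"` or `"dashed"`.
#' @param line_thickness Border/line thickness in board units, `>= 0`.
#' @return An object of class `gpml_graphics`.
#' @export
gpml_graphics <- function(center_x = 0, center_y = 0, width = 80, height = 20,
                          fill_color = "FFFFFF", border_color = "000000",
                          shape_name = "Rectangle", z_order = 0L,
                          line_style = "solid", line_thickness = 1) {
  line_style <- match.arg(line_style, c("solid", "dashed"))
  structure(list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
                 width = as.numeric(width), height = as.numeric(height),
                 fill_color = normalize_color(fill_color, "FFFFFF"),
                 border_color = normalize_color(border_color, "000000"),
                 shape_name = as.character(shape_name), z_order = as.integer(z_order),
                 line_style = line_style, line_thickness = as.numeric(line_thickness)),
            class = "gpml_graphics")
}

#' State attached to a data node (e.g. a phosphorylation site)
#'
#' States are retained as attributes of their parent data node and never
#' become graph nodes in either view.
#'
#' @param graph_ref Graph id of the parent data node.
#' @param text_label State label.
#' @param rel_x,rel_y Relative position on the parent's border, in `[-1, 1]`.
#' @return An object of class `gpml_state`.
#' @export
gpml_state <- function(graph_ref, text_label = "", rel_x = 0, rel_y = 0) {
  structure(list(graph_ref = as.character(graph_ref),
                 text_label = as.character(text_label),
                 rel_x = as.numeric(rel_x), rel_y = as.numeric(rel_y)),
            class = "gpml_state")
}

.ENTITY_TYPES <- c("GeneProduct", "Protein", "Rna", "Metabolite", "Pathway", "Unknown")

#' Data node: a biological entity drawn in the pathway
#'
#' @param graph_id Unique element id.
#' @param text_label Displayed label (typically a gene symbol).
#' @param entity_type One of GeneProduct, Protein, Rna, Metabolite, Pathway,
#'   Unknown.
#' @param xref A [gpml_xref()] annotation.
#' @param graphics A [gpml_graphics()] record.
#' @param group_ref Optional id of the containing group.
#' @param states List of [gpml_state()] attached to this node.
#' @return An object of class `gpml_data_node`.
#' @export
gpml_data_node <- function(graph_id, text_label, entity_type = "GeneProduct",
                           xref = gpml_xref(), graphics = gpml_graphics(),
                           group_ref = NULL, states = list()) {
  if (!entity_type %in% .ENTITY_TYPES) entity_type <- "Unknown"
  structure(list(graph_id = as.character(graph_id), text_label = as.character(text_label),
                 entity_type = entity_type, xref = xref, group_ref = group_ref,
                 graphics = graphics, states = states),
            class = "gpml_data_node")
}

#' Anchor: an attachment point on an interaction line
#'
#' @param graph_id Unique element id.
#' @param position Fraction in `[0, 1]` along the parent interaction.
#' @param shape Anchor shape name (GPML: `"None"`, `"Circle"`).
#' @return An object of class `gpml_anchor`.
#' @export
gpml_anchor <- function(graph_id, position = 0.5, shape = "None") {
  structure(list(graph_id = as.character(graph_id),
                 position = as.numeric(position), shape = as.character(shape)),
            class = "gpml_anchor")
}

.ARROW_HEADS <- c("none", "Arrow", "TBar", "mim-inhibition", "mim-catalysis",
                  "mim-conversion", "mim-stimulation")

#' Interaction endpoint / waypoint
#'
#' @param x,y Position in board units.
#' @param graph_ref Optional id of the element this point attaches to.
#' @param arrow_head Optional arrow-head name (`"Arrow"`, `"TBar"`, the
#'   `mim-*` vocabulary, or any other string carried verbatim).
#' @return An object of class `gpml_point`.
#' @export
gpml_point <- function(x = 0, y = 0, graph_ref = NULL, arrow_head = NULL) {
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 graph_ref = graph_ref, arrow_head = arrow_head),
            class = "gpml_point")
}

#' Interaction: a biological relation drawn as a line
#'
#' The first and last point are the semantic source and target; anchors
#' belong to exactly one interaction.
#'
#' @param graph_id Unique element id.
#' @param points Ordered list of at least two [gpml_point()].
#' @param anchors List of [gpml_anchor()] on this line.
#' @param xref A [gpml_xref()].
#' @param group_ref Optional containing group id.
#' @param graphics A [gpml_graphics()] (line style, color, thickness).
#' @return An object of class `gpml_interaction`.
#' @export
gpml_interaction <- function(graph_id, points, anchors = list(),
                             xref = gpml_xref(), group_ref = NULL,
                             graphics = gpml_graphics(width = 1, height = 1)) {
  stopifnot(length(points) >= 2)
  structure(list(graph_id = as.character(graph_id), points = points,
                 anchors = anchors, xref = xref, group_ref = group_ref,
                 graphics = graphics),
            class = "gpml_interaction")
}

#' Graphical line: a drawn line with no biological meaning
#'
#' Same shape as an interaction but carries no xref and never contributes
#' edges to the network view.
#'
#' @inheritParams gpml_interaction
#' @return An object of class `gpml_graphical_line`.
#' @export
gpml_graphical_line <- function(graph_id, points, anchors = list(),
                                graphics = gpml_graphics(width = 1, height = 1)) {
  stopifnot(length(points) >= 2)
  structure(list(graph_id = as.character(graph_id), points = points,
                 anchors = anchors, graphics = graphics),
            class = "gpml_graphical_line")
}

#' Text label annotation
#' @param graph_id Unique element id.
#' @param text_label Displayed text.
#' @param graphics A [gpml_graphics()].
#' @return An object of class `gpml_label`.
#' @export
gpml_label <- function(graph_id, text_label, graphics = gpml_graphics()) {
  structure(list(graph_id = as.character(graph_id),
                 text_label = as.character(text_label), graphics = graphics),
            class = "gpml_label")
}

#' Shape annotation (boxes, ovals, cell compartments ...)
#' @param graph_id Unique element id.
#' @param graphics A [gpml_graphics()].
#' @return An object of class `gpml_shape`.
#' @export
gpml_shape <- function(graph_id, graphics = gpml_graphics()) {
  structure(list(graph_id = as.character(graph_id), graphics = graphics),
            class = "gpml_shape")
}

#' Group: a GPML container (complex or generic group)
#'
#' Members are the elements whose `group_ref` equals this group's
#' `group_id`.
#'
#' @param group_id Unique group id (the id members reference).
#' @param graph_id Optional graph id (used when other elements point at the
#'   group as an interaction endpoint).
#' @param style Group style: `"Group"`, `"Complex"`, `"Pathway"` or `"None"`.
#' @return An object of class `gpml_group`.
#' @export
gpml_group <- function(group_id, graph_id = NULL, style = "Group") {
  style <- match.arg(style, c("Group", "Complex", "Pathway", "None"))
  structure(list(group_id = as.character(group_id), graph_id = graph_id,
                 style = style),
            class = "gpml_group")
}

#' Pathway document: one parsed GPML pathway
#'
#' @param name Pathway title.
#' @param organism Organism name.
#' @param board_width,board_height Drawing-board extent in board units.
#' @param data_nodes,interactions,graphical_lines,labels,shapes,groups
#'   Lists of the corresponding element types, in document order.
#' @param gpml_version GPML namespace version (only `"2013a"` is supported).
#' @return An object of class `pathway_document`.
#' @export
pathway_document <- function(name = "", organism = "", board_width = 1000,
                             board_height = 1000, data_nodes = list(),
                             interactions = list(), graphical_lines = list(),
                             labels = list(), shapes = list(), groups = list(),
                             gpml_version = "2013a") {
  structure(list(name = as.character(name), organism = as.character(organism),
                 gpml_version = gpml_version,
                 board_width = as.numeric(board_width),
                 board_height = as.numeric(board_height),
                 data_nodes = data_nodes, interactions = interactions,
                 graphical_lines = graphical_lines, labels = labels,
                 shapes = shapes, groups = groups),
            class = "pathway_document")
}

#' @export
print.pathway_document <- function(x, ...) {
  cat("GPML pathway document (", x$gpml_version, ")\n", sep = "")
  cat("  name:     ", x$name, "\n", sep = "")
  cat("  organism: ", x$organism, "\n", sep = "")
  cat(sprintf("  board:    %g x %g\n", x$board_width, x$board_height))
  cat(sprintf("  elements: %d data nodes, %d interactions, %d graphical lines,\n",
              length(x$data_nodes), length(x$interactions), length(x$graphical_lines)))
  cat(sprintf("            %d labels, %d shapes, %d groups\n",
              length(x$labels), length(x$shapes), length(x$groups)))
  invisible(x)
}

# All graph ids carried by elements of a document (excluding group_ids),
# in document order, with NULLs removed.
.doc_graph_ids <- function(doc) {
  ids <- c(
    vapply(doc$data_nodes, `[[`, "", "graph_id"),
    vapply(doc$interactions, `[[`, "", "graph_id"),
    unlist(lapply(doc$interactions, function(i)
      vapply(i$anchors, `[[`, "", "graph_id")), use.names = FALSE),
    vapply(doc$graphical_lines, `[[`, "", "graph_id"),
    unlist(lapply(doc$graphical_lines, function(i)
      vapply(i$anchors, `[[`, "", "graph_id")), use.names = FALSE),
    vapply(doc$labels, `[[`, "", "graph_id"),
    vapply(doc$shapes, `[[`, "", "graph_id"),
    unlist(lapply(doc$groups, function(g)
      if (is.null(g$graph_id)) character(0) else g$graph_id), use.names = FALSE)
  )
  ids[nzchar(ids)]
}

.doc_group_ids <- function(doc) vapply(doc$groups, `[[`, "", "group_id")

#' Resolve a graph reference to its element
#'
#' Looks up the unique element whose `graph_id` (or, for a group, whose
#' `graph_id` or `group_id`) equals `graph_ref`. Anchors nested inside
#' interactions and graphical lines are searched too.
#'
#' @param doc A [pathway_document()].
#' @param graph_ref Reference string.
#' @return The element, or `NULL` when the reference does not resolve.
#' @export
resolve_ref <- function(doc, graph_ref) {
  if (is.null(graph_ref) || !nzchar(graph_ref)) return(NULL)
  for (coll in c("data_nodes", "labels", "shapes")) {
    for (el in doc[[coll]]) if (el$graph_id == graph_ref) return(el)
  }
  for (coll in c("interactions", "graphical_lines")) {
    for (el in doc[[coll]]) {
      if (el$graph_id == graph_ref) return(el)
      for (a in el$anchors) if (a$graph_id == graph_ref) return(a)
    }
  }
  for (g in doc$groups) {
    if (identical(g$group_id, graph_ref)) return(g)
    if (!is.null(g$graph_id) && g$graph_id == graph_ref) return(g)
  }
  NULL
}

.issue <- function(severity, element_id, message) {
  data.frame(severity = severity, element_id = element_id, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a pathway document
#'
#' Checks the structural invariants the converters rely on: document-wide
#' uniqueness of graph ids and group ids, resolution of every
#' `graph_ref`/`group_ref`, anchor positions within `[0, 1]`, state
#' positions within `[-1, 1]`, well-formed colors and positive extents.
#' Issues are returned, never raised; the document is not mutated.
#'
#' @param doc A [pathway_document()].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `element_id` and `message`; zero rows iff all invariants hold.
#' @export
validate_pathway <- function(doc) {
  stopifnot(inherits(doc, "pathway_document"))
  issues <- list()
  add <- function(sev, id, msg) issues[[length(issues) + 1L]] <<- .issue(sev, id, msg)

  gids <- .doc_graph_ids(doc)
  dup <- unique(gids[duplicated(gids)])
  for (d in dup) add("error", d, sprintf("graph_id '%s' is not unique within the document", d))

  grp_ids <- .doc_group_ids(doc)
  dupg <- unique(grp_ids[duplicated(grp_ids)])
  for (d in dupg) add("error", d, sprintf("group_id '%s' is not unique", d))

  all_ids <- unique(c(gids, grp_ids))

  check_group_ref <- function(el) {
    if (!is.null(el$group_ref) && !(el$group_ref %in% grp_ids))
      add("error", el$graph_id,
          sprintf("element '%s' references missing group '%s'", el$graph_id, el$group_ref))
  }
  check_graphics <- function(el) {
    g <- el$graphics
    if (is.null(g)) return(invisible())
    for (col in c("fill_color", "border_color"))
      if (!grepl("^[0-9A-F]{6}$", g[[col]]))
        add("error", el$graph_id, sprintf("element '%s': %s '%s' is not RRGGBB", el$graph_id, col, g[[col]]))
    if (!inherits(el, c("gpml_interaction", "gpml_graphical_line")) &&
        (!is.finite(g$width) || !is.finite(g$height) || g$width <= 0 || g$height <= 0))
      add("error", el$graph_id, sprintf("element '%s': width/height must be > 0", el$graph_id))
  }

  for (dn in doc$data_nodes) {
    check_group_ref(dn); check_graphics(dn)
    for (st in dn$states) {
      if (!identical(st$graph_ref, dn$graph_id))
        add("error", dn$graph_id,
            sprintf("state on '%s' has graph_ref '%s' not matching its parent", dn$graph_id, st$graph_ref))
      if (abs(st$rel_x) > 1 || abs(st$rel_y) > 1)
        add("error", dn$graph_id, sprintf("state on '%s': rel_x/rel_y outside [-1, 1]", dn$graph_id))
    }
  }
  for (coll in c("interactions", "graphical_lines")) {
    for (ia in doc[[coll]]) {
      if (!is.null(ia$group_ref)) check_group_ref(ia)
      for (a in ia$anchors)
        if (a$position < 0 || a$position > 1)
          add("error", a$graph_id, sprintf("anchor '%s': position %g outside [0, 1]", a$graph_id, a$position))
      for (p in ia$points)
        if (!is.null(p$graph_ref) && nzchar(p$graph_ref) && !(p$graph_ref %in% all_ids))
          add("error", ia$graph_id,
              sprintf("point on '%s' references missing element '%s'", ia$graph_id, p$graph_ref))
    }
  }
  for (el in doc$labels) check_graphics(el)
  for (el in doc$shapes) check_graphics(el)

  if (length(issues) == 0)
    return(data.frame(severity = character(0), element_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

# TRUE when the document has no error-severity issues.
.doc_is_valid <- function(doc) {
  iss <- validate_pathway(doc)
  !any(iss$severity == "error")
}

.stop_if_invalid <- function(doc) {
  iss <- validate_pathway(doc)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0)
    stop("invalid pathway document: ", err$message[1],
         if (nrow(err) > 1) sprintf(" (and %d more issues)", nrow(err) - 1L) else "",
         call. = FALSE)
  invisible(doc)
}
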
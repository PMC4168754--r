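#' @title GPML 2013a input/output
#' @description Reads and writes GPML XML (namespace
#'   `http://pathvisio.org/GPML/2013a`) to and from [pathway_document()]
#'   objects. Unknown elements are skipped with a warning, never an error;
#'   attributes absent in the file take fixed defaults (fill `FFFFFF`,
#'   border `000000`, z-order 0, solid lines) so downstream styles are
#'   deterministic.
#' @name gpml-io
NULL

.GPML_NS <- "http://pathvisio.org/GPML/2013a"

.attr_or <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

.num_attr <- function(node, name, default = 0) {
  v <- .attr_or(node, name)
  if (is.null(v)) return(default)
  suppressWarnings(n <- as.numeric(v))
  if (is.na(n)) default else n
}

.parse_graphics <- function(gfx_node, line_like = FALSE) {
  if (is.null(gfx_node) || length(gfx_node) == 0)
    return(gpml_graphics(width = if (line_like) 1 else 80,
                         height = if (line_like) 1 else 20))
  style <- .attr_or(gfx_node, "LineStyle", "Solid")
  gpml_graphics(
    center_x = .num_attr(gfx_node, "CenterX"),
    center_y = .num_attr(gfx_node, "CenterY"),
    width = .num_attr(gfx_node, "Width", if (line_like) 1 else 80),
    height = .num_attr(gfx_node, "Height", if (line_like) 1 else 20),
    fill_color = normalize_color(.attr_or(gfx_node, "FillColor"), "FFFFFF"),
    border_color = normalize_color(.attr_or(gfx_node, "Color"), "000000"),
    shape_name = .attr_or(gfx_node, "ShapeType", "Rectangle"),
    z_order = as.integer(.num_attr(gfx_node, "ZOrder", 0)),
    line_style = if (identical(style, "Broken")) "dashed" else "solid",
    line_thickness = .num_attr(gfx_node, "LineThickness", 1)
  )
}

.parse_xref <- function(el) {
  xr <- xml2::xml_find_first(el, "./d1:Xref", c(d1 = .GPML_NS))
  if (length(xr) == 0 || inherits(xr, "xml_missing")) return(gpml_xref())
  gpml_xref(.attr_or(xr, "Database", ""), .attr_or(xr, "ID", ""))
}

#' Parse GPML text into a pathway document
#'
#' @param xml_text GPML 2013a XML as a single string, or an `xml_document`.
#' @return A [pathway_document()]. Document order of elements is preserved;
#'   elements lacking a `GraphId` receive synthetic ids `auto:<n>` (with a
#'   warning). Unknown GPML elements are skipped with a warning.
#' @seealso [read_gpml()] to parse from a file, [write_gpml()] for the
#'   inverse.
#' @export
parse_gpml <- function(xml_text) {
  x <- if (inherits(xml_text, "xml_document")) xml_text else
    tryCatch(xml2::read_xml(xml_text),
             error = function(e) stop("GPML parse error: ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_name(x)
  ns <- xml2::xml_ns(x)
  if (!identical(root, "Pathway"))
    stop("unsupported format: root element is <", root, ">, expected <Pathway>", call. = FALSE)
  default_ns <- tryCatch(xml2::xml_attr(x, "xmlns"), error = function(e) NA)
  ns_uri <- unname(unlist(ns))
  if (!.GPML_NS %in% ns_uri)
    stop("unsupported GPML namespace: only ", .GPML_NS, " (GPML 2013a) is supported",
         call. = FALSE)
  nsmap <- c(d1 = .GPML_NS)

  auto_counter <- 0L
  gid <- function(el) {
    v <- .attr_or(el, "GraphId")
    if (!is.null(v) && nzchar(v)) return(v)
    auto_counter <<- auto_counter + 1L
    id <- sprintf("auto:%d", auto_counter)
    warning("element <", xml2::xml_name(el), "> lacks GraphId; assigned '", id, "'",
            call. = FALSE)
    id
  }

  parse_points_anchors <- function(el) {
    gfx <- xml2::xml_find_first(el, "./d1:Graphics", nsmap)
    pts <- lapply(xml2::xml_find_all(gfx, "./d1:Point", nsmap), function(p) {
      gr <- .attr_or(p, "GraphRef")
      ah <- .attr_or(p, "ArrowHead")
      gpml_point(.num_attr(p, "X"), .num_attr(p, "Y"), graph_ref = gr, arrow_head = ah)
    })
    anc <- lapply(xml2::xml_find_all(gfx, "./d1:Anchor", nsmap), function(a) {
      gpml_anchor(gid(a), position = .num_attr(a, "Position", 0.5),
                  shape = .attr_or(a, "Shape", "None"))
    })
    list(points = pts, anchors = anc, graphics = .parse_graphics(gfx, line_like = TRUE))
  }

  data_nodes <- list(); interactions <- list(); glines <- list()
  labels <- list(); shapes <- list(); groups <- list(); states <- list()

  known <- c("DataNode", "State", "Interaction", "GraphicalLine", "Label",
             "Shape", "Group", "Graphics", "InfoBox", "Biopax", "BiopaxRef",
             "Legend", "Comment", "Attribute")
  for (el in xml2::xml_children(x)) {
    nm <- xml2::xml_name(el)
    switch(nm,
      DataNode = {
        gfx <- xml2::xml_find_first(el, "./d1:Graphics", nsmap)
        data_nodes[[length(data_nodes) + 1L]] <- gpml_data_node(
          graph_id = gid(el),
          text_label = .attr_or(el, "TextLabel", ""),
          entity_type = .attr_or(el, "Type", "Unknown"),
          xref = .parse_xref(el),
          graphics = .parse_graphics(gfx),
          group_ref = .attr_or(el, "GroupRef")
        )
      },
      State = {
        states[[length(states) + 1L]] <- gpml_state(
          graph_ref = .attr_or(el, "GraphRef", ""),
          text_label = .attr_or(el, "TextLabel", ""),
          rel_x = .num_attr(xml2::xml_find_first(el, "./d1:Graphics", nsmap), "RelX"),
          rel_y = .num_attr(xml2::xml_find_first(el, "./d1:Graphics", nsmap), "RelY")
        )
      },
      Interaction = {
        pa <- parse_points_anchors(el)
        interactions[[length(interactions) + 1L]] <- gpml_interaction(
          graph_id = gid(el), points = pa$points, anchors = pa$anchors,
          xref = .parse_xref(el), group_ref = .attr_or(el, "GroupRef"),
          graphics = pa$graphics
        )
      },
      GraphicalLine = {
        pa <- parse_points_anchors(el)
        glines[[length(glines) + 1L]] <- gpml_graphical_line(
          graph_id = gid(el), points = pa$points, anchors = pa$anchors,
          graphics = pa$graphics
        )
      },
      Label = {
        labels[[length(labels) + 1L]] <- gpml_label(
          graph_id = gid(el), text_label = .attr_or(el, "TextLabel", ""),
          graphics = .parse_graphics(xml2::xml_find_first(el, "./d1:Graphics", nsmap))
        )
      },
      Shape = {
        shapes[[length(shapes) + 1L]] <- gpml_shape(
          graph_id = gid(el),
          graphics = .parse_graphics(xml2::xml_find_first(el, "./d1:Graphics", nsmap))
        )
      },
      Group = {
        groups[[length(groups) + 1L]] <- gpml_group(
          group_id = .attr_or(el, "GroupId", gid(el)),
          graph_id = .attr_or(el, "GraphId"),
          style = {
            s <- .attr_or(el, "Style", "None")
            if (s %in% c("Group", "Complex", "Pathway")) s else "None"
          }
        )
      },
      {
        if (!nm %in% known)
          warning("skipping unknown GPML element <", nm, ">", call. = FALSE)
      }
    )
  }

  # attach states to their parent data nodes
  for (st in states) {
    hit <- FALSE
    for (i in seq_along(data_nodes)) {
      if (data_nodes[[i]]$graph_id == st$graph_ref) {
        data_nodes[[i]]$states <- c(data_nodes[[i]]$states, list(st))
        hit <- TRUE
        break
      }
    }
    if (!hit) warning("state references unknown element '", st$graph_ref, "'; dropped",
                      call. = FALSE)
  }

  gfx <- xml2::xml_find_first(x, "./d1:Graphics", nsmap)
  pathway_document(
    name = .attr_or(x, "Name", ""),
    organism = .attr_or(x, "Organism", ""),
    board_width = .num_attr(gfx, "BoardWidth", 1000),
    board_height = .num_attr(gfx, "BoardHeight", 1000),
    data_nodes = data_nodes, interactions = interactions,
    graphical_lines = glines, labels = labels, shapes = shapes, groups = groups
  )
}

#' Read a GPML file
#' @param path Path to a `.gpml` file.
#' @return A [pathway_document()].
#' @export
read_gpml <- function(path) {
  if (!file.exists(path)) stop("GPML file not found: ", path, call. = FALSE)
  parse_gpml(paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
}

# shortest round-trip decimal representation of a coordinate
.fmt_num <- function(x) {
  if (is.null(x) || !is.finite(x)) return("0")
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  # prune trailing zeros that format() may keep
  if (grepl("\\.", s)) s <- sub("0+$", "", sub("\\.$", "", s))
  sub("\\.$", "", s)
}

.gfx_attrs <- function(g, line_like = FALSE) {
  a <- list(FillColor = g$fill_color, Color = g$border_color,
            ZOrder = as.character(g$z_order),
            LineThickness = .fmt_num(g$line_thickness))
  if (g$line_style == "dashed") a$LineStyle <- "Broken"
  if (!line_like) {
    a <- c(list(CenterX = .fmt_num(g$center_x), CenterY = .fmt_num(g$center_y),
                Width = .fmt_num(g$width), Height = .fmt_num(g$height),
                ShapeType = g$shape_name), a)
  }
  a
}

.add_child <- function(parent, name, attrs = list()) {
  ch <- xml2::xml_add_child(parent, name)
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (!is.null(v) && !is.na(v)) xml2::xml_set_attr(ch, nm, v)
  }
  ch
}

#' Serialize a pathway document to GPML text
#'
#' The output re-parses to a model structurally equal to `doc`
#' (field-by-field, ignoring attribute order and whitespace). An invalid
#' document is refused with the first validation issue in the message.
#'
#' @param doc A valid [pathway_document()].
#' @param path Optional file path; when given the text is also written there.
#' @return GPML XML as a single string (invisibly when `path` is given).
#' @export
write_gpml <- function(doc, path = NULL) {
  iss <- validate_pathway(doc)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0)
    stop("refusing to serialize invalid document: ", err$message[1], call. = FALSE)

  x <- xml2::xml_new_root("Pathway", xmlns = .GPML_NS,
                          Name = doc$name, Organism = doc$organism,
                          Version = doc$gpml_version)
  .add_child(x, "Graphics", list(BoardWidth = .fmt_num(doc$board_width),
                                 BoardHeight = .fmt_num(doc$board_height)))

  write_points_anchors <- function(parent, el) {
    gfx <- .add_child(parent, "Graphics", .gfx_attrs(el$graphics, line_like = TRUE))
    for (p in el$points) {
      a <- list(X = .fmt_num(p$x), Y = .fmt_num(p$y))
      if (!is.null(p$graph_ref)) a$GraphRef <- p$graph_ref
      if (!is.null(p$arrow_head)) a$ArrowHead <- p$arrow_head
      .add_child(gfx, "Point", a)
    }
    for (an in el$anchors)
      .add_child(gfx, "Anchor", list(Position = .fmt_num(an$position),
                                     Shape = an$shape, GraphId = an$graph_id))
  }
  write_xref <- function(parent, xref)
    .add_child(parent, "Xref", list(Database = xref$datasource, ID = xref$identifier))

  states_to_write <- list()
  for (dn in doc$data_nodes) {
    el <- .add_child(x, "DataNode",
                     list(TextLabel = dn$text_label, GraphId = dn$graph_id,
                          Type = dn$entity_type, GroupRef = dn$group_ref))
    .add_child(el, "Graphics", .gfx_attrs(dn$graphics))
    write_xref(el, dn$xref)
    states_to_write <- c(states_to_write, dn$states)
  }
  for (st in states_to_write) {
    el <- .add_child(x, "State", list(GraphRef = st$graph_ref, TextLabel = st$text_label))
    .add_child(el, "Graphics", list(RelX = .fmt_num(st$rel_x), RelY = .fmt_num(st$rel_y)))
  }
  for (ia in doc$interactions) {
    el <- .add_child(x, "Interaction", list(GraphId = ia$graph_id, GroupRef = ia$group_ref))
    write_points_anchors(el, ia)
    write_xref(el, ia$xref)
  }
  for (gl in doc$graphical_lines) {
    el <- .add_child(x, "GraphicalLine", list(GraphId = gl$graph_id))
    write_points_anchors(el, gl)
  }
  for (lb in doc$labels) {
    el <- .add_child(x, "Label", list(TextLabel = lb$text_label, GraphId = lb$graph_id))
    .add_child(el, "Graphics", .gfx_attrs(lb$graphics))
  }
  for (sh in doc$shapes) {
    el <- .add_child(x, "Shape", list(GraphId = sh$graph_id))
    .add_child(el, "Graphics", .gfx_attrs(sh$graphics))
  }
  for (gr in doc$groups)
    .add_child(x, "Group", list(GroupId = gr$group_id, GraphId = gr$graph_id,
                                Style = if (gr$style == "None") NULL else gr$style))
  txt <- as.character(x)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
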
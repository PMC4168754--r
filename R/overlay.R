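#' @title Identifier mapping and experimental-data overlay
#' @description Joins an experimental data table (log fold-change, p-value,
#'   adjusted p-value per identifier) onto the molecule nodes of a converted
#'   pathway, after an optional table-driven identifier translation (e.g.
#'   Entrez Gene to Ensembl), and derives the visual mapping: node fill on a
#'   blue-white-red gradient over the logFC, a highlight border for
#'   significant measurements (adjusted p-value strictly below alpha), and
#'   grey fill for unmeasured nodes.
#' @name overlay
NULL

#' Visual-mapping parameters for the data overlay
#'
#' @param gradient_low_color Fill at `-L` (default blue `0000FF`).
#' @param mid_color Fill at 0 (default white `FFFFFF`).
#' @param high_color Fill at `+L` (default red `FF0000`).
#' @param domain_limit Positive half-width `L` of the gradient domain;
#'   `NULL` (default) means the maximum absolute logFC over measured nodes
#'   at style time.
#' @param alpha Significance threshold on the adjusted p-value (strict
#'   `<`); default 0.05.
#' @param significant_border_color Border for significant nodes (default
#'   green `00FF00`).
#' @param missing_fill_color Fill for unmeasured nodes (default grey
#'   `C8C8C8`).
#' @param default_border_color Border for non-significant nodes.
#' @return An object of class `visual_mapping`.
#' @export
visual_mapping <- function(gradient_low_color = "0000FF", mid_color = "FFFFFF",
                           high_color = "FF0000", domain_limit = NULL,
                           alpha = 0.05, significant_border_color = "00FF00",
                           missing_fill_color = "C8C8C8",
                           default_border_color = "000000") {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(domain_limit)) stopifnot(is.finite(domain_limit), domain_limit > 0)
  structure(list(gradient_low_color = normalize_color(gradient_low_color),
                 mid_color = normalize_color(mid_color),
                 high_color = normalize_color(high_color),
                 domain_limit = domain_limit, alpha = alpha,
                 significant_border_color = normalize_color(significant_border_color),
                 missing_fill_color = normalize_color(missing_fill_color),
                 default_border_color = normalize_color(default_border_color)),
            class = "visual_mapping")
}

.hex_to_rgb <- function(hex) {
  c(strtoi(substr(hex, 1, 2), 16L), strtoi(substr(hex, 3, 4), 16L),
    strtoi(substr(hex, 5, 6), 16L))
}

.rgb_to_hex <- function(rgb) paste0(sprintf("%02X", as.integer(rgb)), collapse = "")

#' Map a log fold-change to a gradient color
#'
#' Piecewise-linear interpolation per RGB channel: `-L` maps to the low
#' color, 0 to the mid color, `+L` to the high color; values beyond the
#' domain clamp to the endpoints. Channels are rounded half-up.
#'
#' @param logFC Log fold-change (scalar).
#' @param vm A [visual_mapping()]; `vm$domain_limit` must be set here.
#' @return Hex RRGGBB string, or `NA` for a non-finite `logFC` (treated as
#'   missing).
#' @export
gradient_color <- function(logFC, vm = visual_mapping(domain_limit = 1)) {
  L <- vm$domain_limit
  stopifnot(!is.null(L), L > 0)
  if (is.null(logFC) || !is.finite(logFC)) return(NA_character_)
  x <- max(-L, min(L, logFC))
  mid <- .hex_to_rgb(vm$mid_color)
  endp <- if (x >= 0) .hex_to_rgb(vm$high_color) else .hex_to_rgb(vm$gradient_low_color)
  t <- abs(x) / L
  channels <- floor(mid + t * (endp - mid) + 0.5)  # round half-up
  .rgb_to_hex(pmin(255, pmax(0, channels)))
}

#' Read an experimental data table
#'
#' TSV/CSV with a header; expected columns: an identifier column (name
#' configurable), `logFC`, `p_value` (or `P.Value`/`pvalue`), `adj_p_value`
#' (or `adj.P.Val`/`padj`). Rows whose p-values fall outside `[0, 1]` are
#' rejected with a warning. Extra numeric columns are kept.
#'
#' @param path File path.
#' @param id_col Name of the identifier column (default `"id"`).
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A data frame with canonical columns `identifier`, `logFC`,
#'   `p_value`, `adj_p_value`.
#' @export
read_data_table <- function(path, id_col = "id", sep = "\t") {
  if (!file.exists(path)) stop("data table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "")
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0)
      stop("data table lacks a column among: ", paste(cands, collapse = ", "),
           call. = FALSE)
    hit[1]
  }
  idc <- pick(c(id_col, "identifier"))
  out <- data.frame(identifier = as.character(df[[idc]]),
                    logFC = as.numeric(df[[pick(c("logFC", "log2FC", "logfc"))]]),
                    p_value = as.numeric(df[[pick(c("p_value", "P.Value", "pvalue", "p.value"))]]),
                    adj_p_value = as.numeric(df[[pick(c("adj_p_value", "adj.P.Val", "padj", "adj.p.value"))]]),
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$p_value) & (out$p_value < 0 | out$p_value > 1) |
    !is.na(out$adj_p_value) & (out$adj_p_value < 0 | out$adj_p_value > 1)
  if (any(bad)) {
    warning(sum(bad), " row(s) with p-values outside [0, 1] rejected", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a two-column identifier mapping table
#'
#' Tab-separated `source_id<TAB>target_id`; lines starting with `#` are
#' comments. A source with several targets keeps them all, de-duplicated,
#' in file order.
#'
#' @param path File path.
#' @return A named list: source id to character vector of target ids.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop("mapping table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
      warning("skipping malformed mapping line: ", ln, call. = FALSE)
      next
    }
    src <- parts[1]; tgt <- parts[2]
    if (!tgt %in% out[[src]]) out[[src]] <- c(out[[src]], tgt)
  }
  out
}

#' Translate molecule-node identifiers through a mapping table
#'
#' Each molecule node's xref identifier is looked up; `mapped_id` becomes
#' the first target in the mapping list (first-by-file-order tie-break).
#' Nodes with no entry get `unmapped = TRUE`. A one-to-many mapping marks
#' the node `ambiguous = TRUE`; the count of such nodes is stored in
#' `graph$meta$ambiguous_mappings`.
#'
#' @param graph A [network_graph()] whose molecule nodes carry
#'   `xref_identifier` attributes.
#' @param mapping A mapping list from [read_mapping_table()].
#' @return The graph with `mapped_id` / `unmapped` / `ambiguous` node
#'   attributes set.
#' @export
map_identifiers <- function(graph, mapping) {
  stopifnot(inherits(graph, "network_graph"))
  if (length(mapping) == 0)
    warning("empty mapping table: all nodes will be unmapped", call. = FALSE)
  n_ambiguous <- 0L
  for (id in ng_node_ids(graph)) {
    if (graph$nodes[[id]]$kind != "molecule") next
    src <- ng_node_attr(graph, id, "xref_identifier")
    targets <- if (!is.null(src) && nzchar(src)) mapping[[src]] else NULL
    if (is.null(targets) || length(targets) == 0) {
      graph <- ng_set_node_attr(graph, id, unmapped = TRUE)
    } else {
      graph <- ng_set_node_attr(graph, id, mapped_id = targets[1])
      if (length(targets) > 1) {
        n_ambiguous <- n_ambiguous + 1L
        graph <- ng_set_node_attr(graph, id, ambiguous = TRUE)
      }
    }
  }
  graph$meta$ambiguous_mappings <- n_ambiguous
  graph
}

#' Join an experimental data table onto molecule nodes
#'
#' Exact-match join on `mapped_id` (falling back to the node's own xref
#' identifier when [map_identifiers()] has not been run). Matching nodes
#' receive `logFC`, `p_value` and `adj_p_value` attributes; unmatched
#' nodes receive none. The join is idempotent. Duplicate identifiers in
#' the data table are an error, raised before any node is touched.
#'
#' @param graph A [network_graph()].
#' @param data A data frame from [read_data_table()] (columns `identifier`,
#'   `logFC`, `p_value`, `adj_p_value`).
#' @return The graph with measurement attributes set on matched nodes.
#' @export
join_data <- function(graph, data) {
  stopifnot(inherits(graph, "network_graph"))
  idcol <- intersect(c("identifier", "id"), names(data))
  if (length(idcol) == 0)
    stop("data table needs an 'identifier' (or 'id') column", call. = FALSE)
  keys <- as.character(data[[idcol[1]]])
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0)
    stop("duplicate identifier(s) in data table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  idx <- stats::setNames(seq_len(nrow(data)), keys)
  for (id in ng_node_ids(graph)) {
    if (graph$nodes[[id]]$kind != "molecule") next
    key <- ng_node_attr(graph, id, "mapped_id")
    if (is.null(key)) key <- ng_node_attr(graph, id, "xref_identifier")
    if (is.null(key) || !nzchar(key) || is.na(idx[key])) next
    i <- idx[[key]]
    graph <- ng_set_node_attr(graph, id, logFC = data$logFC[i],
                              p_value = data$p_value[i],
                              adj_p_value = data$adj_p_value[i])
  }
  graph
}

# measured molecule node ids (finite logFC attribute present)
.measured_ids <- function(graph) {
  ids <- ng_node_ids(graph)
  ids[vapply(ids, function(id) {
    graph$nodes[[id]]$kind == "molecule" && {
      v <- ng_node_attr(graph, id, "logFC")
      !is.null(v) && is.finite(v)
    }
  }, TRUE)]
}

#' Derive the data-overlay style table
#'
#' Measured molecule nodes get a gradient fill from their logFC; unmeasured
#' ones the configured grey. The border turns to the highlight color iff
#' `adj_p_value < alpha` (strict). Annotation, group and connector nodes
#' are left untouched. Deterministic and idempotent given the same graph.
#'
#' @param graph A [network_graph()] after [join_data()].
#' @param vm A [visual_mapping()]. A `NULL` `domain_limit` is replaced by
#'   the maximum absolute logFC over measured nodes (1 when none).
#' @return A `style_table` with `fill_color` and `border_color` rows for
#'   every molecule node.
#' @export
apply_data_styles <- function(graph, vm = visual_mapping()) {
  stopifnot(inherits(graph, "network_graph"), inherits(vm, "visual_mapping"))
  measured <- .measured_ids(graph)
  if (is.null(vm$domain_limit)) {
    L <- if (length(measured) > 0)
      max(abs(vapply(measured, function(id) ng_node_attr(graph, id, "logFC"), 0)))
    else 1
    if (!is.finite(L) || L <= 0) L <- 1
    vm$domain_limit <- L
  }
  buf <- style_buffer()
  for (id in ng_node_ids(graph)) {
    if (graph$nodes[[id]]$kind != "molecule") next
    if (id %in% measured) {
      fill <- gradient_color(ng_node_attr(graph, id, "logFC"), vm)
      adj <- ng_node_attr(graph, id, "adj_p_value")
      sig <- !is.null(adj) && is.finite(adj) && adj < vm$alpha
      buf <- record_style(buf, id, "fill_color", fill)
      buf <- record_style(buf, id, "border_color",
                          if (sig) vm$significant_border_color else vm$default_border_color)
    } else {
      buf <- record_style(buf, id, "fill_color", vm$missing_fill_color)
      buf <- record_style(buf, id, "border_color", vm$default_border_color)
    }
  }
  apply_styles(graph, buf)
}

#' Style nodes by centrality (hub visualization)
#'
#' Node size is linear in degree, mapping the observed `[min, max]` degree
#' range onto `[20, 80]` units (monotone: a higher degree never gets a
#' smaller size); fill color is linear in betweenness through the same
#' gradient machinery. A constant metric places all nodes mid-range.
#'
#' @param graph A [network_graph()].
#' @param centrality A data frame from [centrality_table()] (columns
#'   `node_id`, `degree`, `betweenness`).
#' @param vm A [visual_mapping()] supplying the gradient colors.
#' @return A `style_table` with `size` and `fill_color` rows per node in
#'   `centrality`.
#' @export
centrality_styles <- function(graph, centrality, vm = visual_mapping()) {
  stopifnot(inherits(graph, "network_graph"))
  deg <- centrality$degree; btw <- centrality$betweenness
  size_of <- function(d) {
    if (max(deg) == min(deg)) return(50)
    20 + (d - min(deg)) / (max(deg) - min(deg)) * 60
  }
  vm$domain_limit <- 1
  fill_of <- function(b) {
    if (max(btw) == min(btw)) return(gradient_color(0, vm))
    # map [min, max] onto the full gradient domain [-1, 1]
    gradient_color(-1 + 2 * (b - min(btw)) / (max(btw) - min(btw)), vm)
  }
  buf <- style_buffer()
  for (i in seq_len(nrow(centrality))) {
    id <- centrality$node_id[i]
    buf <- record_style(buf, id, "size", size_of(deg[i]))
    buf <- record_style(buf, id, "fill_color", fill_of(btw[i]))
  }
  apply_styles(graph, buf)
}
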
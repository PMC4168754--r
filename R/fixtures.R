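#' @title Deterministic synthetic pathway generator
#' @description Builds small, fully valid GPML pathway documents in code so
#'   every converter and exporter is testable without network access. The
#'   generated documents exercise the features that matter downstream:
#'   data nodes with shared cross-references (redundancy), groups,
#'   interactions with anchors, labels and shapes. A companion generator
#'   produces a matching experimental data table (logFC, p-value,
#'   Benjamini-Hochberg adjusted p-value) and an Entrez-to-Ensembl-style
#'   mapping table with synthetic `ENSGTEST` identifiers.
#' @name fixtures
NULL

#' Specification of a synthetic pathway
#'
#' @param n_datanodes Number of data nodes (`>= 0`).
#' @param n_redundant_pairs Number of disjoint pairs of data nodes sharing
#'   an xref; at most `n_datanodes / 2`.
#' @param n_groups Number of groups; each takes `group_size` data nodes
#'   (from the end of the node list), so
#'   `n_groups * group_size <= n_datanodes`.
#' @param group_size Members per group, at least 2.
#' @param n_interactions Number of interactions; endpoints are chosen among
#'   nodes with distinct merge keys, so at least two distinct keys are
#'   required when positive.
#' @param n_anchors Number of anchors, at most `n_interactions` (one per
#'   interaction, at position 0.5).
#' @param n_labels,n_shapes Number of label / shape annotations.
#' @param seed RNG seed making generation deterministic.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_datanodes = 5, n_redundant_pairs = 1, n_groups = 1,
                         group_size = 2, n_interactions = 3, n_anchors = 1,
                         n_labels = 1, n_shapes = 1, seed = 7L) {
  spec <- list(n_datanodes = as.integer(n_datanodes),
               n_redundant_pairs = as.integer(n_redundant_pairs),
               n_groups = as.integer(n_groups), group_size = as.integer(group_size),
               n_interactions = as.integer(n_interactions),
               n_anchors = as.integer(n_anchors), n_labels = as.integer(n_labels),
               n_shapes = as.integer(n_shapes), seed = as.integer(seed))
  if (any(unlist(spec[1:8]) < 0)) stop("fixture counts must be non-negative", call. = FALSE)
  if (spec$group_size < 2) stop("group_size must be at least 2", call. = FALSE)
  if (spec$n_redundant_pairs > spec$n_datanodes / 2)
    stop("n_redundant_pairs exceeds n_datanodes / 2", call. = FALSE)
  if (spec$n_anchors > spec$n_interactions)
    stop("n_anchors exceeds n_interactions", call. = FALSE)
  if (spec$n_groups * spec$group_size > spec$n_datanodes)
    stop("groups require more data nodes than available", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic pathway document
#'
#' Deterministic for a fixed spec: the same spec always yields a
#' byte-identical GPML serialization. The result always passes
#' [validate_pathway()] with zero issues; exactly `n_redundant_pairs`
#' disjoint pairs of data nodes share an xref; positions lie on a grid;
#' every interaction endpoint resolves.
#'
#' @param spec A [fixture_spec()].
#' @return A [pathway_document()].
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_datanodes

  # xref assignment: pairs (1,2), (3,4), ... share; the rest are distinct
  entrez <- character(n)
  for (j in seq_len(spec$n_redundant_pairs)) {
    entrez[2 * j - 1] <- as.character(1000 + j)
    entrez[2 * j] <- as.character(1000 + j)
  }
  rest <- which(!nzchar(entrez))
  entrez[rest] <- as.character(2000 + rest)

  grid_xy <- function(i, per_row = 4, x0 = 100, y0 = 80, dx = 150, dy = 100) {
    r <- (i - 1) %/% per_row; c <- (i - 1) %% per_row
    list(x = x0 + c * dx, y = y0 + r * dy)
  }

  # groups occupy the trailing nodes so members keep distinct merge keys
  group_of <- rep(NA_character_, n)
  if (spec$n_groups > 0) {
    start <- n - spec$n_groups * spec$group_size + 1L
    for (gi in seq_len(spec$n_groups)) {
      idx <- start + (gi - 1L) * spec$group_size + seq_len(spec$group_size) - 1L
      group_of[idx] <- sprintf("grp%d", gi)
    }
  }

  data_nodes <- lapply(seq_len(n), function(i) {
    xy <- grid_xy(i)
    gpml_data_node(
      graph_id = sprintf("dn%d", i),
      text_label = sprintf("GENE%s", entrez[i]),
      entity_type = "GeneProduct",
      xref = gpml_xref("Entrez Gene", entrez[i]),
      graphics = gpml_graphics(center_x = xy$x, center_y = xy$y,
                               width = 80, height = 20),
      group_ref = if (is.na(group_of[i])) NULL else group_of[i]
    )
  })

  groups <- lapply(seq_len(spec$n_groups), function(gi)
    gpml_group(sprintf("grp%d", gi), graph_id = sprintf("grpnode%d", gi),
               style = "Complex"))

  # interaction endpoints walk the distinct merge keys; the source of the
  # first interaction is the *second* member of the first redundant pair
  # when one exists, so merging is exercised on a live edge
  key_first <- !duplicated(entrez)
  reps <- which(key_first)            # representative node index per key
  m <- length(reps)
  if (spec$n_interactions > 0 && m < 2)
    stop("interactions require at least two distinct merge keys", call. = FALSE)
  arrow_cycle <- c("Arrow", "TBar", "mim-inhibition", "mim-catalysis", "mim-stimulation")
  interactions <- lapply(seq_len(spec$n_interactions), function(k) {
    si <- ((k - 1) %% (m - 1)) + 1L   # source key index 1..m-1
    ti <- si + 1L
    src_i <- reps[si]
    if (k == 1 && spec$n_redundant_pairs > 0) src_i <- 2L  # duplicate member
    tgt_i <- reps[ti]
    sxy <- grid_xy(src_i); txy <- grid_xy(tgt_i)
    anchors <- if (k <= spec$n_anchors)
      list(gpml_anchor(sprintf("anc%d", k), position = 0.5, shape = "None"))
    else list()
    gpml_interaction(
      graph_id = sprintf("int%d", k),
      points = list(
        gpml_point(sxy$x, sxy$y, graph_ref = sprintf("dn%d", src_i)),
        gpml_point(txy$x, txy$y, graph_ref = sprintf("dn%d", tgt_i),
                   arrow_head = arrow_cycle[((k - 1) %% length(arrow_cycle)) + 1L])
      ),
      anchors = anchors
    )
  })

  labels <- lapply(seq_len(spec$n_labels), function(i) {
    xy <- grid_xy(n + i)
    gpml_label(sprintf("lbl%d", i), sprintf("Annotation %d", i),
               gpml_graphics(center_x = xy$x, center_y = xy$y + 300,
                             width = 120, height = 16, shape_name = "None"))
  })
  shapes <- lapply(seq_len(spec$n_shapes), function(i) {
    xy <- grid_xy(n + spec$n_labels + i)
    gpml_shape(sprintf("shp%d", i),
               gpml_graphics(center_x = xy$x, center_y = xy$y + 360,
                             width = 200, height = 120, shape_name = "Oval",
                             fill_color = "FFFFFF", border_color = "808080"))
  })

  pathway_document(
    name = sprintf("Synthetic pathway (seed %d)", spec$seed),
    organism = "Homo sapiens",
    board_width = 800, board_height = 700,
    data_nodes = data_nodes, interactions = interactions,
    labels = labels, shapes = shapes, groups = groups
  )
}

#' Generate a demo data table and identifier mapping for a document
#'
#' Emulates the overlay scenario: pathway xrefs (Entrez Gene) are mapped to
#' synthetic Ensembl-style ids (`ENSGTEST...`), and a measurement table is
#' generated with one row per distinct gene xref. `logFC` is drawn from a
#' normal with mean 0 and sd 1.5; raw p-values are derived from the effect
#' size at a fixed standard error of 0.5 and adjusted with
#' Benjamini-Hochberg (so adjusted >= raw). A configurable fraction of
#' xrefs (default 0.2, at least one when positive) is deliberately left
#' out of the *mapping* table so the corresponding nodes stay unmeasured
#' and exercise the grey-fill path.
#'
#' @param doc A [pathway_document()] with at least one xref-annotated data
#'   node.
#' @param seed RNG seed.
#' @param unmeasured_fraction Fraction of distinct xrefs left unmapped.
#' @return A list with `data` (data frame: `id`, `logFC`, `p_value`,
#'   `adj_p_value`) and `mapping` (named list source id -> target ids).
#' @export
make_demo_data <- function(doc, seed = 7L, unmeasured_fraction = 0.2) {
  stopifnot(inherits(doc, "pathway_document"),
            unmeasured_fraction >= 0, unmeasured_fraction < 1)
  ids <- unique(vapply(doc$data_nodes, function(d) d$xref$identifier, ""))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0)
    stop("document has no xref-annotated data nodes", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    targets <- sprintf("ENSGTEST%08d", seq_along(ids))
    n_unmapped <- if (unmeasured_fraction > 0)
      max(1L, round(unmeasured_fraction * length(ids))) else 0L
    unmapped <- if (n_unmapped > 0) sample(ids, n_unmapped) else character(0)
    mapping <- stats::setNames(as.list(targets), ids)
    mapping <- mapping[setdiff(ids, unmapped)]

    logFC <- stats::rnorm(length(ids), mean = 0, sd = 1.5)
    p <- pmin(1, pmax(1e-12, 2 * stats::pnorm(-abs(logFC) / 0.5)))
    adj <- stats::p.adjust(p, method = "BH")
    data <- data.frame(id = targets, logFC = logFC, p_value = p,
                       adj_p_value = adj, stringsAsFactors = FALSE)
  })
  list(data = data, mapping = mapping)
}

#' Write demo data and mapping tables to files
#'
#' @param demo A list from [make_demo_data()].
#' @param data_path,mapping_path Output paths (TSV).
#' @return Invisibly, `c(data_path, mapping_path)`.
#' @export
write_demo_data <- function(demo, data_path, mapping_path) {
  utils::write.table(demo$data, data_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  lines <- c("# source_id\ttarget_id",
             unlist(lapply(names(demo$mapping), function(s)
               sprintf("%s\t%s", s, demo$mapping[[s]])), use.names = FALSE))
  writeLines(lines, mapping_path, useBytes = TRUE)
  invisible(c(data_path, mapping_path))
}
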
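test_that("pathway view keeps every element and counts nodes per rule", {
  # 2 DataNodes + 1 Label + 1 Shape + 1 Interaction -> 4 nodes, 1 edge
  doc <- pathway_document(
    name = "tiny",
    data_nodes = list(
      gpml_data_node("a", "A", graphics = gpml_graphics(center_x = 10, center_y = 20)),
      gpml_data_node("b", "B", graphics = gpml_graphics(center_x = 50, center_y = 20))),
    labels = list(gpml_label("l1", "note")),
    shapes = list(gpml_shape("s1")),
    interactions = list(gpml_interaction("i1", points = list(
      gpml_point(10, 20, graph_ref = "a"),
      gpml_point(50, 20, graph_ref = "b", arrow_head = "Arrow")))))
  pv <- to_pathway_view(doc)
  expect_length(ng_node_ids(pv$graph), 4)
  expect_length(ng_edge_ids(pv$graph), 1)
  kinds <- ng_nodes(pv$graph)
  expect_equal(kinds$kind[kinds$node_id %in% c("l1", "s1")],
               c("annotation", "annotation"))
  expect_equal(pv$graph$edges[["i1"]]$interaction_type, "Arrow")
})

test_that("node positions equal GPML centers bit-for-bit", {
  doc <- make_fixture(fixture_spec())
  pv <- to_pathway_view(doc)
  for (dn in doc$data_nodes) {
    expect_identical(as.numeric(style_value(pv$styles, dn$graph_id, "x")),
                     dn$graphics$center_x)
    expect_identical(as.numeric(style_value(pv$styles, dn$graph_id, "y")),
                     dn$graphics$center_y)
  }
  for (lb in doc$labels)
    expect_identical(as.numeric(style_value(pv$styles, lb$graph_id, "x")),
                     lb$graphics$center_x)
})

test_that("element conservation: one node per data node, label, shape, group, anchor", {
  for (sp in list(fixture_spec(),
                  fixture_spec(n_datanodes = 9, n_redundant_pairs = 2, n_groups = 3,
                               group_size = 3, n_interactions = 5, n_anchors = 4,
                               n_labels = 2, n_shapes = 3, seed = 21))) {
    doc <- make_fixture(sp)
    pv <- to_pathway_view(doc)
    n_anchors <- sum(vapply(doc$interactions, function(i) length(i$anchors), 0L))
    expect_length(ng_node_ids(pv$graph),
                  length(doc$data_nodes) + length(doc$labels) +
                    length(doc$shapes) + length(doc$groups) + n_anchors)
  }
})

test_that("an anchored interaction splits at a connector node", {
  # DERIVED by hand on the 4-element construction: nodes a, b, c plus the
  # anchor; main edge a->anc->b in two segments, inhibition edge c->anc
  pv <- to_pathway_view(anchored_doc())
  g <- pv$graph
  expect_setequal(ng_node_ids(g), c("a", "b", "c", "anc"))
  expect_equal(g$nodes[["anc"]]$kind, "connector")
  ed <- ng_edges(g)
  expect_setequal(ed$edge_id, c("main:1", "main:2", "inhib"))
  expect_equal(ed[ed$edge_id == "main:1", c("source", "target")],
               data.frame(source = "a", target = "anc", row.names = 3L),
               ignore_attr = TRUE)
  expect_equal(ed[ed$edge_id == "main:2", c("source", "target")],
               data.frame(source = "anc", target = "b", row.names = 4L),
               ignore_attr = TRUE)
  expect_equal(g$edges[["inhib"]]$target, "anc")
  expect_equal(g$edges[["inhib"]]$interaction_type, "mim-inhibition")
  # anchor sits at the midpoint of the straight a->b segment
  expect_equal(as.numeric(style_value(pv$styles, "anc", "x")), 200)
  expect_equal(as.numeric(style_value(pv$styles, "anc", "y")), 100)
})

test_that("graphical lines become undirected edges flagged graphical", {
  doc <- anchored_doc()
  doc$graphical_lines <- list(gpml_graphical_line("gl1", points = list(
    gpml_point(0, 0, graph_ref = "a"), gpml_point(1, 1, graph_ref = "c"))))
  pv <- to_pathway_view(doc)
  e <- pv$graph$edges[["gl1"]]
  expect_false(e$directed)
  expect_true(isTRUE(e$attributes$graphical))
})

test_that("every pathway-view node has complete position and color styles", {
  doc <- make_fixture(fixture_spec())
  pv <- to_pathway_view(doc)
  for (id in ng_node_ids(pv$graph))
    for (prop in c("x", "y", "width", "height", "fill_color"))
      expect_false(is.na(style_value(pv$styles, id, prop)),
                   label = sprintf("style %s for node %s", prop, id))
})
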
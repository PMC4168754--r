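test_that("merge keys prefer the xref and fall back to type + label", {
  dn <- gpml_data_node("x1", "CDK2", xref = gpml_xref("Entrez Gene", "1017"))
  expect_equal(merge_key(dn), "xref|Entrez Gene|1017")

  dn2 <- gpml_data_node("x2", "other label", xref = gpml_xref("Entrez Gene", "1017"))
  expect_equal(merge_key(dn), merge_key(dn2))  # same xref, different everything else

  atp <- gpml_data_node("m1", "ATP", entity_type = "Metabolite", xref = gpml_xref())
  expect_equal(merge_key(atp), "label|Metabolite|ATP")
  atp_lower <- gpml_data_node("m2", "atp", entity_type = "Metabolite", xref = gpml_xref())
  expect_false(merge_key(atp) == merge_key(atp_lower))  # case-sensitive
})

test_that("network view drops annotations and merges redundant nodes", {
  # DERIVED enumeration: 5 data nodes (one redundant pair), 1 label, 1 shape,
  # 1 group of 2, 3 interactions, no anchors
  # -> 4 molecule + 1 group = 5 nodes; 3 interaction + 2 contains = 5 edges
  doc <- make_fixture(fixture_spec(n_anchors = 0))
  nv <- to_network_view(doc)
  kinds <- ng_nodes(nv$graph)
  expect_equal(sum(kinds$kind == "molecule"), 4)
  expect_equal(sum(kinds$kind == "group"), 1)
  expect_equal(sum(kinds$kind == "annotation"), 0)
  expect_length(ng_node_ids(nv$graph), 5)
  ed <- ng_edges(nv$graph)
  expect_equal(sum(ed$interaction_type == "contains"), 2)
  expect_equal(nrow(ed), 5)
  expect_false("lbl1" %in% kinds$node_id)
  expect_false("shp1" %in% kinds$node_id)
})

test_that("merged nodes record provenance and take the first contributor's face", {
  doc <- make_fixture(fixture_spec())
  nv <- to_network_view(doc)
  expect_true("dn1" %in% ng_node_ids(nv$graph))   # representative id
  expect_false("dn2" %in% ng_node_ids(nv$graph))  # merged away
  expect_equal(ng_node_attr(nv$graph, "dn1", "merged_ids"), "dn1,dn2")
  expect_equal(ng_node_attr(nv$graph, "dn1", "n_merged"), 2L)
  expect_equal(ng_node_attr(nv$graph, "dn1", "text_label"),
               doc$data_nodes[[1]]$text_label)
})

test_that("a document with all-distinct xrefs merges nothing", {
  doc <- make_fixture(fixture_spec(n_redundant_pairs = 0, n_anchors = 0))
  nv <- to_network_view(doc)
  expect_equal(sum(ng_nodes(nv$graph)$kind == "molecule"), length(doc$data_nodes))
})

test_that("merge_report partitions all data-node ids", {
  for (sp in list(fixture_spec(), fixture_spec(n_datanodes = 10, n_redundant_pairs = 4,
                                               n_interactions = 5, n_anchors = 0,
                                               seed = 13))) {
    doc <- make_fixture(sp)
    rep <- merge_report(doc)
    ids <- unlist(rep, use.names = FALSE)
    expect_setequal(ids, vapply(doc$data_nodes, `[[`, "", "graph_id"))
    expect_equal(anyDuplicated(ids), 0L)
    expect_equal(sum(vapply(rep, length, 0L) == 2), sp$n_redundant_pairs)
    expect_setequal(names(rep),
                    unique(vapply(doc$data_nodes, merge_key, "")))
  }
  expect_length(merge_report(pathway_document()), 0)
})

test_that("anchors on used interactions become small connector nodes", {
  nv <- to_network_view(anchored_doc())
  g <- nv$graph
  expect_equal(g$nodes[["anc"]]$kind, "connector")
  ed <- ng_edges(g)
  expect_setequal(ed$edge_id, c("main:1", "main:2", "inhib"))
  expect_equal(g$edges[["inhib"]]$target, "anc")
  # "very small nodes": fixed 5x5 units for group and connector nodes
  expect_equal(style_value(nv$styles, "anc", "width"), "5")
  expect_equal(style_value(nv$styles, "anc", "height"), "5")
})

test_that("dangling endpoints are dropped with a warning under the default option", {
  doc <- anchored_doc()
  doc$interactions[[2]]$points[[1]]$graph_ref <- NULL  # source now dangles
  expect_warning(nv <- to_network_view(doc), "dangling")
  expect_false("inhib" %in% ng_edge_ids(nv$graph))

  # both endpoints dangling: interaction dropped entirely
  doc2 <- anchored_doc()
  doc2$interactions[[2]]$points[[1]]$graph_ref <- NULL
  doc2$interactions[[2]]$points[[2]]$graph_ref <- NULL
  expect_warning(nv2 <- to_network_view(doc2), "both endpoints")
})

test_that("parallel edges collapse to one edge with a multiplicity attribute", {
  dn <- function(id, entrez) gpml_data_node(id, id, xref = gpml_xref("Entrez Gene", entrez),
                                            graphics = gpml_graphics(center_x = 1, center_y = 1))
  mk_int <- function(id) gpml_interaction(id, points = list(
    gpml_point(0, 0, graph_ref = "p"), gpml_point(1, 1, graph_ref = "q",
                                                  arrow_head = "Arrow")))
  doc <- pathway_document(data_nodes = list(dn("p", "1"), dn("q", "2")),
                          interactions = list(mk_int("i1"), mk_int("i2")))
  nv <- to_network_view(doc)
  expect_length(ng_edge_ids(nv$graph), 1)
  expect_equal(nv$graph$edges[[1]]$attributes$multiplicity, 2L)

  nv2 <- to_network_view(doc, network_options(collapse_parallel_edges = FALSE))
  expect_length(ng_edge_ids(nv2$graph), 2)
})

test_that("the layout is deterministic, finite and collision-free", {
  doc <- make_fixture(fixture_spec())
  nv <- to_network_view(doc)
  l1 <- apply_layout(nv$graph, seed = 42, iterations = 100)
  l2 <- apply_layout(nv$graph, seed = 42, iterations = 100)
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1$x)) && all(is.finite(l1$y)))
  expect_equal(anyDuplicated(paste(l1$x, l1$y)), 0L)

  single <- ng_add_node(network_graph(), "only", "molecule")
  expect_equal(apply_layout(single, 1, 10),
               data.frame(node_id = "only", x = 0, y = 0, stringsAsFactors = FALSE))
  expect_error(apply_layout(network_graph(), 1, 10), "empty")
})

test_that("two connected nodes land within sane force-directed distance bounds", {
  g <- graph_from_edges(c("a", "b"), list(c("a", "b")))
  l <- apply_layout(g, seed = 5, iterations = 200)
  d <- sqrt(diff(l$x)^2 + diff(l$y)^2)
  expect_gt(d, 1e-6)
  expect_lt(d, 10)  # FR ideal edge length is ~1 for a 2-node graph
})

test_that("the whole conversion is reproducible from (doc, opts)", {
  doc <- make_fixture(fixture_spec())
  nv1 <- to_network_view(doc, network_options(layout_seed = 7))
  nv2 <- to_network_view(doc, network_options(layout_seed = 7))
  expect_identical(nv1$graph, nv2$graph)
  expect_identical(nv1$styles, nv2$styles)
})
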
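test_that("GraphML carries nodes, edges and typed attribute keys", {
  g <- graph_from_edges(c("a", "b"), list(c("a", "b")))
  g <- ng_set_node_attr(g, "a", logFC = 1.25)
  xml <- to_graphml(g)
  doc <- xml2::read_xml(xml)
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 2)
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), 1)
  keys <- xml2::xml_find_all(doc, "//d1:key", ns)
  logfc_key <- keys[xml2::xml_attr(keys, "attr.name") == "logFC"]
  expect_equal(xml2::xml_attr(logfc_key, "attr.type"), "double")
})

test_that("GraphML round-trips through an independent reader", {
  doc <- make_fixture(fixture_spec())
  nv <- to_network_view(doc)
  f <- tempfile(fileext = ".graphml")
  writeLines(to_graphml(nv$graph, nv$styles), f)
  ig <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(ig)$id, ng_node_ids(nv$graph))
  ed <- ng_edges(nv$graph)
  igraph::V(ig)$name <- igraph::V(ig)$id
  got <- igraph::as_data_frame(ig, what = "edges")
  expect_setequal(paste(got$from, got$to),
                  paste(ed$source, ed$target))
  # style attributes survive as string columns
  expect_true("style_fill_color" %in% igraph::vertex_attr_names(ig))
})

test_that("unsupported attribute types are refused by name", {
  g <- ng_add_node(network_graph(), "a", "molecule",
                   attributes = list(weird = list(1, 2)))
  expect_error(to_graphml(g), "weird")
})

test_that("SIF grammar is exact and deterministic on the canonical fixture", {
  doc <- make_fixture(fixture_spec(n_anchors = 0))
  nv <- to_network_view(doc)
  sif <- to_sif(nv$graph)
  lines <- strsplit(sif, "\n", fixed = TRUE)[[1]]
  expect_equal(lines, c("grpnode1\tcontains\tdn4",
                        "grpnode1\tcontains\tdn5",
                        "dn1\tArrow\tdn3",
                        "dn3\tTBar\tdn4",
                        "dn4\tmim-inhibition\tdn5"))
  expect_identical(sif, to_sif(nv$graph))

  iso <- ng_add_node(nv$graph, "zzz-island", "molecule")
  expect_match(to_sif(iso), "\nzzz-island\n$")
  expect_equal(to_sif(network_graph()), "")
})

test_that("node-link JSON matches the shipped schema's shape", {
  schema <- jsonlite::fromJSON(system.file("extdata", "network-graph.schema.json",
                                           package = "gpmlgraph"),
                               simplifyVector = FALSE)
  nv <- to_network_view(make_fixture(fixture_spec()))
  parsed <- jsonlite::fromJSON(to_json_graph(nv$graph, nv$styles),
                               simplifyVector = FALSE)
  expect_setequal(intersect(names(parsed), schema$required), schema$required)
  for (n in parsed$nodes) {
    expect_true(all(c("id", "kind") %in% names(n)))
    expect_true(n$kind %in% c("molecule", "group", "connector", "annotation"))
    expect_type(n$style, "list")  # styles present when supplied
  }
  for (e in parsed$edges) {
    expect_true(all(c("id", "source", "target", "interaction_type", "directed")
                    %in% names(e)))
    expect_type(e$directed, "logical")
  }
  # styles omitted -> no style keys anywhere
  bare <- jsonlite::fromJSON(to_json_graph(nv$graph), simplifyVector = FALSE)
  expect_false(any(vapply(c(bare$nodes, bare$edges),
                          function(o) "style" %in% names(o), TRUE)))
  # empty graph
  expect_equal(jsonlite::fromJSON(to_json_graph(network_graph())),
               list(nodes = list(), edges = list()))
})

test_that("exports are byte-identical across repeated calls", {
  nv <- to_network_view(make_fixture(fixture_spec()))
  expect_identical(to_graphml(nv$graph, nv$styles), to_graphml(nv$graph, nv$styles))
  expect_identical(to_json_graph(nv$graph, nv$styles),
                   to_json_graph(nv$graph, nv$styles))
})

test_that("the node-attribute sidecar tabulates every node", {
  nv <- to_network_view(make_fixture(fixture_spec()))
  f <- tempfile(fileext = ".tsv")
  write_node_attributes_tsv(nv$graph, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_setequal(tab$node_id, ng_node_ids(nv$graph))
  expect_true(all(c("kind", "merge_key") %in% names(tab)))
})
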
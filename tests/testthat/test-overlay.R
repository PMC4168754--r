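# small graph with three molecule nodes carrying Entrez-style identifiers
overlay_graph <- function() {
  g <- network_graph()
  for (i in 1:3)
    g <- ng_add_node(g, sprintf("n%d", i), "molecule",
                     attributes = list(xref_identifier = as.character(1000 + i)))
  ng_add_node(g, "grp", "group")
}

test_that("identifier mapping uses the first target and flags the rest", {
  mapping <- list(`1001` = "ENSGTEST01", `1002` = c("ENSGTEST02", "ENSGTEST03"))
  g <- map_identifiers(overlay_graph(), mapping)
  expect_equal(ng_node_attr(g, "n1", "mapped_id"), "ENSGTEST01")
  expect_equal(ng_node_attr(g, "n2", "mapped_id"), "ENSGTEST02")  # first wins
  expect_true(isTRUE(ng_node_attr(g, "n2", "ambiguous")))
  expect_true(isTRUE(ng_node_attr(g, "n3", "unmapped")))
  expect_equal(g$meta$ambiguous_mappings, 1L)
  expect_warning(map_identifiers(overlay_graph(), list()), "empty mapping")
})

test_that("data joins exactly on mapped ids and is idempotent", {
  mapping <- list(`1001` = "E1", `1002` = "E2")
  data <- data.frame(identifier = c("E1", "E2"), logFC = c(1.3, -2),
                     p_value = c(0.01, 0.2), adj_p_value = c(0.04, 0.3))
  g <- join_data(map_identifiers(overlay_graph(), mapping), data)
  expect_equal(ng_node_attr(g, "n1", "logFC"), 1.3)
  expect_null(ng_node_attr(g, "n3", "logFC"))  # unmapped keeps no data
  g2 <- join_data(g, data)
  expect_identical(g, g2)

  dup <- rbind(data, data[1, ])
  expect_error(join_data(g, dup), "duplicate")
})

test_that("the gradient hits its endpoints, midpoint and clamp exactly", {
  vm <- visual_mapping(domain_limit = 2)
  expect_equal(gradient_color(0, vm), "FFFFFF")
  expect_equal(gradient_color(2, vm), "FF0000")
  expect_equal(gradient_color(-2, vm), "0000FF")
  expect_equal(gradient_color(1, vm), "FF8080")    # linear midpoint to red
  expect_equal(gradient_color(-1, vm), "8080FF")   # blue mirror
  expect_equal(gradient_color(99, vm), "FF0000")   # clamps beyond +L
  expect_equal(gradient_color(-99, vm), "0000FF")
  expect_true(is.na(gradient_color(NaN, vm)))
})

test_that("the gradient is odd around zero for the symmetric default palette", {
  vm <- visual_mapping(domain_limit = 1.7)
  mirror <- function(hex) paste0(substr(hex, 5, 6), substr(hex, 3, 4), substr(hex, 1, 2))
  for (x in c(0.1, 0.33, 0.8, 1.2, 1.7))
    expect_equal(gradient_color(-x, vm), mirror(gradient_color(x, vm)))
})

test_that("data styles follow the gradient / border / grey rules", {
  mapping <- list(`1001` = "E1", `1002` = "E2")
  data <- data.frame(identifier = c("E1", "E2"), logFC = c(2.0, 0.5),
                     p_value = c(0.005, 0.05), adj_p_value = c(0.01, 0.05))
  g <- join_data(map_identifiers(overlay_graph(), mapping), data)
  st <- apply_data_styles(g, visual_mapping(domain_limit = 2))
  expect_equal(style_value(st, "n1", "fill_color"), "FF0000")
  expect_equal(style_value(st, "n1", "border_color"), "00FF00")  # adj_p < 0.05
  # adjusted p of exactly 0.05 is NOT significant (strict inequality)
  expect_equal(style_value(st, "n2", "border_color"), "000000")
  # unmeasured node is grey with default border
  expect_equal(style_value(st, "n3", "fill_color"), "C8C8C8")
  expect_equal(style_value(st, "n3", "border_color"), "000000")
  # group node untouched
  expect_true(is.na(style_value(st, "grp", "fill_color")))
})

test_that("styling partitions molecule nodes into measured and missing", {
  doc <- make_fixture(fixture_spec())
  demo <- make_demo_data(doc, seed = 7)
  nv <- to_network_view(doc)
  g <- join_data(map_identifiers(nv$graph, demo$mapping), demo$data)
  st <- apply_data_styles(g)
  mols <- ng_nodes(g)$node_id[ng_nodes(g)$kind == "molecule"]
  fills <- vapply(mols, function(id) style_value(st, id, "fill_color"), "")
  expect_false(any(is.na(fills)))               # every molecule styled
  measured <- names(fills)[fills != "C8C8C8"]
  missing <- names(fills)[fills == "C8C8C8"]
  expect_setequal(c(measured, missing), mols)   # exact partition
  expect_gte(length(missing), 1)                # demo data leaves >= 1 unmeasured
  # deterministic and idempotent
  expect_identical(st, apply_data_styles(g))
})

test_that("data and mapping tables read from disk with validation", {
  dtf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tlogFC\tp_value\tadj_p_value",
               "E1\t1.5\t0.01\t0.02",
               "E2\t0.1\t1.5\t0.9"), dtf)     # second row has p > 1
  expect_warning(dt <- read_data_table(dtf), "rejected")
  expect_equal(nrow(dt), 1)
  expect_equal(dt$identifier, "E1")

  mpf <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "1001\tE1", "1001\tE2", "1001\tE1", "1002\tE9"), mpf)
  mp <- read_mapping_table(mpf)
  expect_equal(mp[["1001"]], c("E1", "E2"))    # de-duplicated, order kept
  expect_equal(mp[["1002"]], "E9")
})

test_that("centrality styling maps degree to size monotonically", {
  g <- graph_from_edges(c("hub", "a", "b", "c", "d"),
                        list(c("hub", "a"), c("hub", "b"), c("hub", "c"),
                             c("hub", "d"), c("a", "b")))
  ct <- centrality_table(g)
  st <- centrality_styles(g, ct)
  size_of <- function(id) as.numeric(style_value(st, id, "size"))
  expect_equal(size_of("hub"), 80)   # max degree
  expect_equal(size_of("d"), 20)     # min degree
  ord <- order(ct$degree)
  expect_true(all(diff(vapply(ct$node_id[ord], size_of, 0)) >= 0))

  # constant metric -> all mid-range
  tri <- graph_from_edges(c("x", "y", "z"), list(c("x","y"), c("y","z"), c("x","z")))
  st2 <- centrality_styles(tri, centrality_table(tri))
  expect_equal(as.numeric(style_value(st2, "x", "size")), 50)
})
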
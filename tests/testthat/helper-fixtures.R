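# Hand-built documents and mock transports shared across the suite.

# minimal GPML text: Pathway root + one DataNode
minimal_gpml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Mini" Organism="Homo sapiens">\n',
    '  <Graphics BoardWidth="500" BoardHeight="400"/>\n',
    '  <DataNode TextLabel="TP53" GraphId="n1" Type="GeneProduct">\n',
    '    <Graphics CenterX="370.0" CenterY="510.0" Width="80.0" Height="20.0"/>\n',
    '    <Xref Database="Entrez Gene" ID="7157"/>\n',
    '  </DataNode>\n',
    '</Pathway>\n')
}

# two data nodes joined by an interaction carrying one anchor, plus a third
# node whose inhibition edge attaches to that anchor (4-element core)
anchored_doc <- function() {
  dn <- function(id, label, x, y, entrez)
    gpml_data_node(id, label, "GeneProduct", gpml_xref("Entrez Gene", entrez),
                   gpml_graphics(center_x = x, center_y = y))
  pathway_document(
    name = "anchored", organism = "Homo sapiens",
    data_nodes = list(dn("a", "A", 100, 100, "1"), dn("b", "B", 300, 100, "2"),
                      dn("c", "C", 200, 300, "3")),
    interactions = list(
      gpml_interaction("main",
        points = list(gpml_point(100, 100, graph_ref = "a"),
                      gpml_point(300, 100, graph_ref = "b", arrow_head = "Arrow")),
        anchors = list(gpml_anchor("anc", position = 0.5))),
      gpml_interaction("inhib",
        points = list(gpml_point(200, 300, graph_ref = "c"),
                      gpml_point(200, 100, graph_ref = "anc",
                                 arrow_head = "mim-inhibition"))))
  )
}

# build a network_graph from an undirected edge list over given node ids
graph_from_edges <- function(nodes, edges) {
  g <- network_graph()
  for (n in nodes) g <- ng_add_node(g, n, "molecule")
  if (length(edges) > 0)
    for (i in seq_along(edges))
      g <- ng_add_edge(g, sprintf("e%d", i), edges[[i]][1], edges[[i]][2],
                       interaction_type = "Arrow", directed = FALSE)
  g
}

# deterministic Erdos-Renyi-style random graph, n nodes, edge prob p
random_test_graph <- function(n, p = 0.4) {
  nodes <- sprintf("v%d", seq_len(n))
  edges <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (stats::runif(1) < p) edges[[length(edges) + 1]] <- c(nodes[i], nodes[j])
  graph_from_edges(nodes, edges)
}

# Independent brute-force betweenness oracle: exhaustive enumeration of all
# shortest paths per node pair over the BFS distance field. Endpoints are
# excluded, each unordered pair counted once, equal-length paths split the
# count equally. Deliberately naive; only for graphs of ~10 nodes.
oracle_betweenness <- function(graph) {
  nodes <- ng_node_ids(graph)
  adj <- stats::setNames(lapply(nodes, function(n) character(0)), nodes)
  ed <- ng_edges(graph)
  if (nrow(ed) > 0) {
    for (i in seq_len(nrow(ed))) {
      a <- ed$source[i]; b <- ed$target[i]
      if (a == b) next
      if (!b %in% adj[[a]]) { adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a) }
    }
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  bfs <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes); d[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  for (si in seq_along(nodes)) {
    s <- nodes[si]
    d <- bfs(s)
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      t <- nodes[ti]
      if (!is.finite(d[t])) next
      paths <- list()
      walk <- function(v, path) {
        if (v == t) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
        for (w in adj[[v]])
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(path, w))
      }
      walk(s, s)
      np <- length(paths)
      for (p in paths)
        for (v in setdiff(p, c(s, t))) btw[v] <- btw[v] + 1 / np
    }
  }
  btw
}

# ---- mock transports --------------------------------------------------------

# serve canned bodies keyed by a substring of the URL
mock_transport <- function(responses, status = 200L) {
  calls <- new.env(); calls$n <- 0L
  f <- function(url, token, timeout_seconds) {
    calls$n <- calls$n + 1L
    for (key in names(responses))
      if (grepl(key, url, fixed = TRUE))
        return(list(status_code = status, text = responses[[key]]))
    list(status_code = 404L, text = "not here")
  }
  attr(f, "calls") <- calls
  f
}

# transport that never responds: it polls the token every `poll_interval`
# seconds and cancels it itself after `cancel_after` polls (simulating a user
# hitting cancel mid-request); records when the token was set
make_stalled_transport <- function(cancel_after = 3L, poll_interval = 0.02,
                                   max_polls = 200L, state = new.env()) {
  state$cancelled_at <- NULL
  f <- function(url, token, timeout_seconds) {
    polls <- 0L
    repeat {
      polls <- polls + 1L
      if (polls == cancel_after) {
        cancel(token)
        state$cancelled_at <- Sys.time()
      }
      if (is_cancelled(token)) stop("transfer aborted")
      if (polls > max_polls) stop("stalled transport gave up")
      Sys.sleep(poll_interval)
    }
  }
  attr(f, "state") <- state
  f
}
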
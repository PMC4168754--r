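# gpmlgraph

Pathway diagrams as analyzable networks: GPML import, conversion and data
overlay in R.

## The problem

Community-curated pathway databases such as WikiPathways store pathways as
*drawn diagrams* in GPML (Graphical Pathway Markup Language): data nodes
(genes, proteins, metabolites) with coordinates, interactions drawn as lines
with anchors, groups/complexes, plus purely graphical labels and shapes.
That representation is ideal for reading but awkward for network analysis —
the same gene may be drawn several times, interaction lines split at
anchors, and half the elements carry no biology at all.

`gpmlgraph` reads GPML 2013a documents and converts them into two graph
representations:

* **Pathway view** — a faithful graph replica of the diagram. Every data
  node, label, shape, group and anchor becomes a node; node positions in
  the accompanying style table equal the GPML center coordinates
  bit-for-bit, so the original layout is preserved for data visualization.
* **Network view** — a simplified molecule–interaction network. Graphical
  annotations are removed; redundant data nodes are **merged**: two nodes
  merge when they share a non-empty cross-reference Xref =
  (datasource, identifier) — e.g. Entrez Gene 1017 — with a
  (entity type, label) fallback for unannotated nodes. Groups and anchors
  survive as very small connector nodes, and a seeded Fruchterman–Reingold
  layout supplies coordinates, so the whole conversion is deterministic.

Around the two converters the package provides:

* **Deferred styles** — visual properties are recorded into a buffer while
  the graph is still being built (the targets need not exist yet) and
  resolved against the finished graph with last-write-wins semantics.
* **Data overlay** — table-driven identifier mapping (e.g. Entrez→Ensembl)
  followed by an exact join of a measurement table (`logFC`, `p_value`,
  `adj_p_value`). Fill color follows a blue–white–red gradient, linear per
  RGB channel over `[-L, +L]` in logFC; a green border marks significant
  nodes (`adj_p < 0.05`, strict); unmeasured nodes are filled grey.
* **Topology** — undirected degree and unnormalized shortest-path
  betweenness, `C_B(v) = Σ_{s≠v≠t} σ_st(v)/σ_st`, for hub spotting.
* **Exports** — GraphML (typed attribute keys), SIF, node-link JSON with a
  shipped schema; all byte-deterministic.
* **Web-service client** — pathway search and GPML download with a strict
  cancellation contract (sticky tokens, abort within one polling interval,
  no partial cache entries) and a fully injectable transport.
* **Synthetic generator** — deterministic pathway documents plus matching
  demo measurement/mapping tables, used throughout the test suite.

## Worked example

```r
library(gpmlgraph)

doc <- read_gpml(system.file("extdata", "synthetic-canonical.gpml",
                             package = "gpmlgraph"))
doc
#> GPML pathway document (2013a)
#>   name:     Synthetic pathway (seed 7)
#>   organism: Homo sapiens
#>   board:    800 x 700
#>   elements: 5 data nodes, 3 interactions, 0 graphical lines,
#>             1 labels, 1 shapes, 1 groups

nv <- to_network_view(doc)
nv$graph
#> network_graph: 6 nodes, 6 edges
#>   kinds: molecule=4, group=1, connector=1, annotation=0
```

Five drawn data nodes became four molecules: `dn1` and `dn2` share Entrez
Gene id 1001 and merged (`nv$merge` records the provenance); the label and
shape are gone; the group and the interaction anchor survive as small
nodes.

```r
centrality_table(nv$graph)
#>    node_id degree betweenness
#> 1      dn1      1           0
#> 2      dn3      2           6
#> 3      dn4      3           6
#> 4      dn5      2           0
#> 5 grpnode1      2           0
#> 6     anc1      2           4
```

Overlaying the bundled synthetic measurements:

```r
demo <- make_demo_data(doc, seed = 7)
g  <- join_data(map_identifiers(nv$graph, demo$mapping), demo$data)
as.data.frame(apply_data_styles(g))
#>   target_id target_class     property  value
#> 1       dn1         node border_color 000000
#> 2       dn1         node   fill_color DCDCFF
#> 3       dn3         node border_color 000000
#> 4       dn3         node   fill_color C8C8C8
#> 5       dn4         node border_color 00FF00
#> 6       dn4         node   fill_color FF9393
#> 7       dn5         node border_color 00FF00
#> 8       dn5         node   fill_color FF0000
```

`dn5` has the strongest up-regulation (saturated red `FF0000`) and is
significant (green border); `dn1` is mildly down (pale blue), not
significant; `dn3` was deliberately left out of the identifier mapping, so
it is unmeasured and grey (`C8C8C8`).

The same workflow is available from a shell:

```sh
inst/cli/gpmlgraph convert --view network --format sif --out out.sif pathway.gpml
inst/cli/gpmlgraph overlay --data data.tsv --mapping map.tsv --out out.graphml pathway.gpml
inst/cli/gpmlgraph fetch --out WP2795.gpml WP2795
```

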
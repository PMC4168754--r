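---
title: "From pathway diagram to analyzable network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pathway diagram to analyzable network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpmlgraph)
```

## The two representations

A GPML document is a drawing: typed data nodes with board coordinates
(origin top-left, y growing downward, arbitrary "board units"),
interactions as poly-lines whose endpoints may reference other elements,
anchors (attachment points at a fractional position along a line), groups,
and purely decorative labels and shapes. `gpmlgraph` converts such a
document into two graphs that serve different purposes.

**Pathway view.** Every element that has an identity becomes a node —
data nodes as `molecule`, labels and shapes as `annotation`, groups as
`group`, anchors as `connector` — and every interaction and graphical line
contributes edges. The accompanying style table stores each element's
GPML center coordinate *unchanged*: we treat layout fidelity as a hard
invariant (tested bit-for-bit), because the whole point of this view is
that a measurement overlaid on it lands on the diagram the curator drew.
No rescaling, no unit conversion.

**Network view.** Analysis wants one node per biological entity.
Annotations contribute nothing. Data nodes are merged under a two-level
*merge key*:

1. if the node carries a complete cross-reference, the key is the exact
   pair (datasource, identifier) — identity of the referenced database
   record is the only biologically sound notion of redundancy;
2. otherwise the key falls back to (entity type, case-sensitive label),
   which keeps unannotated nodes distinct across types and spellings.

A merged node keeps the first contributor in document order as its
representative (a deterministic, if arbitrary, tie-break) and records all
contributing ids in a `merged_ids` attribute, so merging is auditable via
`merge_report()`. Groups become one node each, joined to members by
undirected `"contains"` edges; anchors on interactions become connector
nodes that split the parent edge into segments, so a catalysis edge
attached mid-line keeps a meaningful endpoint. Both get a fixed small size
(5×5 board units) in the style table — small enough to read as junctions,
large enough to click.

### Assumptions and degenerate inputs

* Only the GPML 2013a namespace is accepted; other namespaces fail fast
  with a clear message rather than half-parsing.
* The first and last point of an interaction are its semantic source and
  target; intermediate waypoints are renderer cosmetics and are ignored.
* When a point carries both coordinates and a `GraphRef`, the reference
  wins: coordinates are cosmetic, references are semantic.
* States (e.g. phosphorylation sites) stay attributes of their parent data
  node; they are never graph nodes in either view.
* Interaction endpoints that resolve to labels or shapes are treated as
  dangling in the network view (an edge into a decoration has no
  molecular meaning). Dangling endpoints drop the edge with a warning by
  default (`drop_dangling_edges`); an interaction dangling at both ends is
  dropped entirely.
* Elements without a `GraphId` get synthetic ids `auto:<n>`, with a
  warning, so downstream references remain total.
* An anchor with no third edge attached still becomes a connector node:
  the structure of the drawn line is preserved rather than silently
  simplified.

## Deferred styles

Both converters build their graph and its appearance in one pass, but
style assignments are not applied directly: they are *recorded* into a
buffer (`record_style()`) while construction is still in progress — the
target may not exist yet — and *resolved* once the graph is complete
(`apply_styles()`). Resolution is strict (a target that still does not
exist is an error naming it), last-write-wins for repeated assignments to
one (target, property) pair, idempotent, and never mutates the graph.
This buffering is what lets the overlay pipeline layer data-driven styles
over structural defaults by simple concatenation of buffers.

## The data overlay

The overlay joins a measurement table — `logFC`, `p_value`,
`adj_p_value`, keyed by identifier — onto molecule nodes, optionally after
a table-driven identifier translation. Mapping is a plain two-column
lookup; one-to-many mappings resolve to the *first* target in file order
and flag the node `ambiguous`, with a count in `graph$meta`. The join is
exact-match and refuses duplicated keys outright rather than guessing.

Fill color is piecewise-linear per RGB channel over logFC: `-L` → blue
(`0000FF`), `0` → white (`FFFFFF`), `+L` → red (`FF0000`), clamped outside
`±L`, channels rounded half-up. The domain half-width `L` defaults to the
maximum |logFC| among measured nodes — a symmetric domain centred on "no
change", so equal up- and down-regulation get mirror-image colors — and
can be fixed explicitly for comparability across datasets. Significance
adds a green border (`00FF00`) iff `adj_p_value < alpha` with **strict**
inequality at the default `alpha = 0.05`; a node at exactly 0.05 is not
highlighted. Unmeasured nodes are filled grey (`C8C8C8`). The exact hexes
for grey and green are configurable defaults. When several merged
originals map to different measurements, the node takes its
representative's value — the same tie-break as merging itself — so overlay
results never depend on hash order.

## Topology

Degree and betweenness are computed through igraph on the undirected
simple graph: collapsed parallel edges count once (multiplicity is an
attribute, not extra adjacency) and loops are dropped. Betweenness is
unnormalized Brandes counting — endpoints excluded, each unordered pair
counted once, equal split among equally short paths — with a `normalize`
flag off by default. The test suite checks it against an independent
brute-force oracle that enumerates *all* shortest paths per pair over a
BFS distance field; the two routes agree to 1e-9 on hundreds of random
graphs of up to 10 nodes, and exactly on path/star/complete closed forms.

## Layout

The network view's coordinates come from Fruchterman–Reingold — the
conventional force-directed default — run for `layout_iterations`
(default 100) under `layout_seed` (default 42). The RNG is scoped with
`withr::with_seed`, so conversion is reproducible end to end and never
perturbs the caller's RNG state. A single node is placed at the origin;
exact coordinate collisions (possible only in degenerate graphs) are
separated by a deterministic nudge of 1e-3·i board units.

## The web-service client

Pathway search and GPML download take a *cancellation token*: an
observable, sticky flag settable from outside the running operation. The
contract, enforced by tests against a deliberately stalled mock transport:

* a pre-cancelled token aborts before any transport call;
* a token set mid-transfer aborts within one polling interval (the suite
  asserts < 250 ms under mock timing, polling every 20 ms);
* cancellation, transport failure and HTTP ≥ 400 raise *distinguishable*
  classed conditions (`gpml_cancelled`, `gpml_transport_error`,
  `gpml_service_error`/`gpml_not_found`);
* the on-disk cache (keyed by pathway id and revision) is written
  atomically only after a complete transfer, so no partial GPML can ever
  be served later.

The transport is an injectable function; the default uses curl with a
progress callback that aborts when the token fires. Endpoint paths are
configuration (templates with `{wpid}`-style placeholders), not code,
because the live API's URL scheme has changed over the years.

## The synthetic generator

`make_fixture()` builds documents with planted structure: exactly
`n_redundant_pairs` disjoint pairs of data nodes sharing an Entrez-style
xref, groups occupying the trailing nodes (so group members keep distinct
merge keys and membership edges are predictable), interactions walking the
distinct merge keys — the first one deliberately starting from the
*duplicate* member of a redundant pair so merging is exercised on a live
edge — and optional anchors, labels and shapes. Generation is fully
deterministic by construction (grid positions, sequential ids), so the
same spec always serializes byte-identically.

`make_demo_data()` emulates the overlay scenario: logFC ~ N(0, 1.5) per
distinct xref (a realistic effect-size spread for a differentiation
contrast), raw p-values derived from the effect size at a fixed standard
error of 0.5, BH-adjusted (so adjusted ≥ raw and the significance path is
exercised with realistic monotonicity). The default unmeasured fraction of
0.2 is implemented by omitting xrefs from the *mapping* table rather than
dropping data rows: the data table keeps one row per distinct gene, while
the unmapped nodes exercise the grey-fill path — both properties hold at
once, as they would with a real mapping service that simply lacks some
ids.

What the generator does **not** emulate: realistic pathway topology
(degree distributions, pathway size — real pathways have tens to hundreds
of nodes; fixtures have 3–15), curved edge routing, nested groups,
multi-point interactions with waypoints, or GPML written by other tools
with vendor quirks. Passing tests therefore demonstrate the conversion
laws and contracts, not robustness to every GPML document in the wild.

## Problem sizes

The test suite and the acceptance script run entirely on generated
documents: 50 round-trip fixtures of 3–11 data nodes, 200 random graphs of
≤ 10 nodes for the betweenness oracle (exhaustive path enumeration is
exponential, so small n is the honest regime for a brute-force oracle),
and single canonical fixtures elsewhere. These sizes were chosen so the
oracle stays exact and the suite stays fast; every law tested is
size-independent.

## Known limitations

* GPML 2021 is not supported (different namespace and element model).
* `write_gpml()` emits the attribute subset the model holds; comments,
  literature references and BioPAX payloads are skipped on parsing (with
  a warning for genuinely unknown elements) and therefore not round-tripped.
* Centrality treats all edges as undirected; a directed variant is out of
  scope.
* Identifier mapping is table-driven only; no live mapping service is
  consulted.
* The pathway view reproduces positions, sizes, colors and labels, not
  fonts or curved edge geometry.
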
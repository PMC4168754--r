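Package: gpmlgraph
Title: Pathway Diagrams as Analyzable Networks: GPML Import, Conversion
    and Data Overlay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads WikiPathways pathway diagrams in the GPML 2013a XML
    format and converts them into two graph representations: an annotated
    pathway view that reproduces the drawn diagram (layout, labels, shapes)
    and a simplified molecule-interaction network in which graphical
    annotations are removed and redundant data nodes sharing a
    cross-reference are merged.  Supports overlay of experimental data
    (log fold-changes with significance highlighting), table-driven
    identifier mapping, degree and betweenness centrality, export to
    GraphML, SIF and node-link JSON, a deterministic synthetic-pathway
    generator for testing, and a cancellable WikiPathways web-service
    client.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    curl,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
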
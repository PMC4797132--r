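Package: modnet
Title: Network Module Discovery, Clustering, Enrichment and Layout for
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless engine for seed-driven network module discovery in
    biological interaction networks. Imports and persists background
    interaction sources (SIF/TSV/GraphML), extracts shortest-path
    subnetworks around recurrently altered genes with hypergeometric
    linker-significance filtering, weights edges by expression correlation,
    clusters with Markov clustering (MCL) and MCODE, promotes clusters to
    group (compound) nodes, performs Gene Ontology over-representation
    analysis from OBO/GAF inputs, computes group-aware force-directed
    layouts with animation frames, and maps omics values to visual
    attributes with per-condition overlay export. Includes a deterministic
    synthetic-fixture generator (planted-partition networks plus a factor
    model for expression and alteration tables) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
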
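Package: trcascade
Title: Temporal Regulatory Cascades from Time-Series Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies stage-specific transcriptional regulators in
    time-series gene-expression experiments and assembles them into a
    temporal regulatory cascade: a stage-ordered graph whose columns hold
    regulators peaking at one time point and whose edges are supported by a
    precomputed background regulatory network. Profiles are matched by
    Pearson correlation against one-hot template peak patterns, filtered by
    expression floor (minE), correlation floor (minC) and per-stage cap
    (maxS), and linked by within-stage and consecutive-stage network edges.
    Includes per-stage Gene Ontology over-representation (one-sided Fisher's
    exact test, Bonferroni), construction of the background network from
    scored binding-site predictions (per-PWM top-fraction retention),
    dataset randomization controls (profile reassignment, matrix
    permutation, random values), a planted-signal synthetic benchmark, and
    exports to SIF, GraphML, Cytoscape JSON and a round-trippable edge
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
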
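Package: arbscore
Title: Arborescence-Based Hierarchy Detection in Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates how hierarchical a directed network is by reducing it
    to an arborescence forest: strongly connected components are condensed
    into single nodes, the resulting acyclic graph is rooted by keeping, for
    every node with several parents, only the incoming edge from the
    lowest out-closeness predecessor, and the score is the fraction of the
    original edges that survive.  Ships the standard comparison measures
    (flow hierarchy, global reaching centrality, agony given a ranking), a
    degree-preserving double-edge-switch null model with a two-sigma
    hierarchy classification, synthetic graph generators (directed
    Erdos-Renyi, direction-randomized Watts-Strogatz, old-to-new oriented
    preferential attachment, toy hierarchies), edge-list input/output,
    DOT and Newick forest export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
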
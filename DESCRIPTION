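Package: homophilynet
Title: Kin Networks, Homophilic Friend Choice, and the Clustering Transition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulator of social network formation in which
    agents embedded in a fertility-driven kin network (sibling and
    first-cousin edges defined by shared grandparents) complete their ego
    networks to a uniform degree target using one of three friend-choice
    heuristics: trait homophily, graph-distance-weighted homophily, or
    random choice.  Computes the friend ratio (the fraction of edges that
    are non-kin) and several clustering coefficient variants, and drives
    fertility sweeps that trace the u-shaped clustering transition as kin
    availability falls.  Includes u-shape detection on binned sweep
    records, GraphML and edge-list import/export, and a command-line
    interface for single runs, sweeps, and transition plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    ggplot2,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
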
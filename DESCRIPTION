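Package: netflow
Title: Network-Flow Reliability Bounds for Complex Membership in Probabilistic Protein Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts new members of partially known protein complexes and
    pathways in probabilistic interaction networks. Computes provable lower
    bounds on two-terminal network reliability from maximum sets of
    edge-disjoint paths (unit-capacity max flow), scales threshold queries
    with hierarchical clustering and bound-based pruning, and ships Monte
    Carlo simulation and random-walk-with-restart baselines plus a
    brute-force exact-reliability oracle and a synthetic scale-free network
    generator for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
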
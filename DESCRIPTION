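Package: leidenr
Title: Leiden and Louvain Community Detection with Connectivity Guarantees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection on undirected weighted graphs by modularity or
    Constant Potts Model (CPM) optimisation. Implements the Louvain algorithm
    (greedy local moving plus aggregation) and the Leiden algorithm (fast local
    move queue, theta-randomized refinement within communities, and aggregation
    on the refined partition), together with checkers for the hierarchy of
    guarantees the Leiden algorithm provides (gamma-separation, connectivity,
    node optimality, subpartition gamma-density, uniform gamma-density, subset
    optimality), an audit that flags disconnected and badly connected
    communities by consistently re-clustering each community's subnetwork, a
    planted-partition benchmark generator with a resolution-from-mixing rule,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
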
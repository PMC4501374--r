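Package: kassembly
Title: Minimal k-Cores, Threshold Dynamics and k-Assemblies on Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the graph-theoretic study of associative memory via
    k-assemblies. A neuronal network is modelled as a simple undirected graph
    on which a threshold function spreads activation: a vertex fires when at
    least k of its neighbours are active. The package implements the
    activation calculus (iteration, closure, invariant/persistent/weak set
    classification), greedy maximum k-core peeling, Bron-Kerbosch maximal
    clique enumeration, and a backtracking algorithm that enumerates all
    minimal k-cores of a graph without repetition, together with two
    independent baseline enumerators for cross-validation. A seeded
    simulation harness summarises minimal k-core counts over Bernoulli and
    random regular graph ensembles and reports how the enumerated cores
    overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
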
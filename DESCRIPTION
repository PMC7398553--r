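Package: sirpredict
Title: Exact SIR Outbreak Sizes and Their Predictability from Node
    Centralities on Small Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the exact expected outbreak size of the Markovian
    SIR (susceptible-infectious-recovered) epidemic model for every seed
    node of every nonisomorphic connected simple undirected graph of a
    given size, by exhaustively unfolding the configuration tree with
    merging of identical configurations.  Provides the exhaustive graph
    ensemble (with graph6 import/export for externally generated sets),
    a suite of normalized node centralities (degree, eigenvector,
    PageRank, Katz, closeness, betweenness, coreness) plus edge density,
    and a supervised-learning protocol (random-forest and support-vector
    regression with cross-validated grid search, learning curves and
    permutation tests) that measures how well centrality values predict
    the outbreak size across the whole ensemble.  Includes independent
    validation oracles (absorbing Markov chain linear solve, Gillespie
    simulation) and prediction maps over two-feature planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    randomForest,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
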
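# Normalized node centralities used as predictors of epidemic importance.
#
# All eight features are mapped to [0,1] so that raw values are
# comparable across graphs of the same size:
#   degree        deg(i) / (N-1)
#   eigenvector   principal eigenvector of A, 2-norm 1 (Perron sign)
#   pagerank      x = D (D - alpha A)^{-1} 1, normalized to sum 1
#   katz          x = (I - alpha A)^{-1} 1, normalized to 2-norm 1
#   closeness     (N-1) / sum_j d_ij
#   betweenness   pair-dependency sum / ((N-1)(N-2)/2)
#   coreness      k-core index / (N-1)
#   density       (M/N) / ((N-1)/2) = 2M / (N(N-1))   [per graph]
# Betweenness and coreness are scaled by their theoretical maxima, not
# per-graph maxima: per-graph scaling would pin a value of 1 in every
# graph and destroy cross-graph comparability, which is the whole point
# of predicting from raw centrality values.

#' Centrality parameters
#'
#' @param pagerank_alpha damping factor for PageRank (0 < alpha < 1).
#' @param katz_alpha attenuation factor for Katz centrality; must stay
#'   below 1/lambda_1 for every graph processed (checked per graph).
#' @return object of class `centrality_config`.
#' @export
centrality_config <- function(pagerank_alpha = 0.85, katz_alpha = 0.1) {
  stopifnot(pagerank_alpha > 0, pagerank_alpha < 1, katz_alpha > 0)
  structure(list(pagerank_alpha = pagerank_alpha, katz_alpha = katz_alpha),
            class = "centrality_config")
}

adjacency_dense <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' Normalized degree centrality
#'
#' Node degree divided by the maximum possible degree N - 1.
#' @param g a connected `igraph` object.
#' @return numeric vector, one value per node, in (0, 1].
#' @export
degree_centrality <- function(g) {
  n <- igraph::vcount(g)
  as.numeric(igraph::degree(g)) / (n - 1)
}

#' Eigenvector centrality (unit Euclidean norm)
#'
#' Principal eigenvector of the adjacency matrix with the Perron sign
#' convention (all entries positive), normalized to 2-norm 1.  Requires
#' a connected graph so the Perron vector is unique and positive.
#' @param g a connected `igraph` object.
#' @return numeric vector with unit 2-norm.
#' @export
eigenvector_centrality <- function(g) {
  if (!igraph::is_connected(g)) stop("graph must be connected")
  A <- adjacency_dense(g)
  es <- eigen(A, symmetric = TRUE)
  x <- es$vectors[, 1L]
  if (sum(x) < 0) x <- -x
  if (any(x <= 0))
    stop("principal eigenvector is not strictly positive; eigensolver failed")
  x / sqrt(sum(x^2))
}

#' PageRank centrality (matrix-resolvent form, sum one)
#'
#' Solves x = D (D - alpha A)^{-1} 1 directly (D the diagonal degree
#' matrix) and normalizes the result to sum to one per graph.
#' @param g a connected `igraph` object.
#' @param config a [centrality_config()].
#' @return numeric vector summing to 1.
#' @export
pagerank_centrality <- function(g, config = centrality_config()) {
  A <- adjacency_dense(g)
  d <- rowSums(A)
  x <- d * solve(diag(d) - config$pagerank_alpha * A, rep(1, nrow(A)))
  x / sum(x)
}

#' Katz centrality (unit Euclidean norm)
#'
#' Solves x = (I - alpha A)^{-1} 1 and normalizes to 2-norm 1.  Errors
#' if alpha >= 1/lambda_1, where the resolvent series diverges.
#' @inheritParams pagerank_centrality
#' @return numeric vector with unit 2-norm.
#' @export
katz_centrality <- function(g, config = centrality_config()) {
  A <- adjacency_dense(g)
  lambda1 <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (config$katz_alpha * lambda1 >= 1)
    stop(sprintf("katz_alpha = %g >= 1/lambda_1 = %g: Katz series diverges",
                 config$katz_alpha, 1 / lambda1))
  x <- solve(diag(nrow(A)) - config$katz_alpha * A, rep(1, nrow(A)))
  x / sqrt(sum(x^2))
}

#' Closeness centrality
#'
#' (N - 1) divided by the sum of shortest-path distances to all other
#' nodes; lies in (0, 1] on a connected graph.
#' @param g a connected `igraph` object.
#' @return numeric vector.
#' @export
closeness_centrality <- function(g) {
  if (!igraph::is_connected(g)) stop("graph must be connected")
  d <- igraph::distances(g)
  (nrow(d) - 1) / rowSums(d)
}

#' Betweenness centrality (scaled by the theoretical maximum)
#'
#' Sum over unordered node pairs (excluding the node itself) of the
#' fraction of shortest paths passing through the node, divided by
#' (N-1)(N-2)/2 — the value attained by the center of a star.
#' @param g a connected `igraph` object.
#' @return numeric vector in [0, 1].
#' @export
betweenness_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 2) return(numeric(n)) # no third node can lie between a pair
  as.numeric(igraph::betweenness(g, directed = FALSE)) / ((n - 1) * (n - 2) / 2)
}

#' Coreness (scaled by the theoretical maximum)
#'
#' Largest k such that the node belongs to a k-core (a maximal subgraph
#' of minimum degree k), divided by N - 1.
#' @param g a connected `igraph` object.
#' @return numeric vector in (0, 1].
#' @export
coreness_centrality <- function(g) {
  n <- igraph::vcount(g)
  as.numeric(igraph::coreness(g)) / (n - 1)
}

#' Normalized edge density
#'
#' M/N (half the average degree) rescaled by its maximum (N-1)/2, i.e.
#' 2M / (N(N-1)): the fraction of possible edges present.  A per-graph
#' quantity shared by all nodes of the graph.
#' @param g an `igraph` object.
#' @return scalar in (0, 1].
#' @export
graph_edge_density <- function(g) {
  n <- as.numeric(igraph::vcount(g))
  2 * as.numeric(igraph::gsize(g)) / (n * (n - 1))
}

#' All eight predictor features for the nodes of one graph
#'
#' @param g a connected `igraph` object.
#' @param config a [centrality_config()].
#' @return data frame with one row per node and columns `graph_id`,
#'   `node`, `degree`, `eigenvector`, `pagerank`, `katz`, `closeness`,
#'   `betweenness`, `coreness`, `density`.
#' @export
node_features <- function(g, config = centrality_config()) {
  n <- as.integer(igraph::vcount(g))
  data.frame(
    graph_id = graph_id(g),
    node = seq_len(n),
    degree = degree_centrality(g),
    eigenvector = eigenvector_centrality(g),
    pagerank = pagerank_centrality(g, config),
    katz = katz_centrality(g, config),
    closeness = closeness_centrality(g),
    betweenness = betweenness_centrality(g),
    coreness = coreness_centrality(g),
    density = graph_edge_density(g))
}

#' Feature table for a collection of graphs
#'
#' @param graphs list of connected `igraph` objects.
#' @param config a [centrality_config()].
#' @return row-bound data frame of [node_features()] results.
#' @export
featurize <- function(graphs, config = centrality_config()) {
  do.call(rbind, lapply(graphs, node_features, config = config))
}

#' Names of the eight predictor features
#' @return character vector.
#' @export
feature_names <- function() {
  c("degree", "eigenvector", "pagerank", "katz",
    "closeness", "betweenness", "coreness", "density")
}
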
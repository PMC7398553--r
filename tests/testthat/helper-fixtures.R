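# Shared fixtures, computed lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ensemble6 <- function() fixture("ensemble6", enumerate_connected_graphs(6))

omega6 <- function() fixture("omega6", solve_graphs(ensemble6(), sir_parameters()))

features6 <- function() fixture("features6", featurize(ensemble6()))

records6 <- function() fixture("records6", assemble_records(features6(), omega6()))

# a small named collection of hand-built graphs used across tests
path_graph <- function(n) igraph::make_lattice(n)

triangle_pendant_graph <- function() {
  # triangle {1,2,3}; pendant edge 1-4; pendant 2-path 2-5-6.
  # Asymmetric: its automorphism group is trivial.
  igraph::make_graph(c(1, 2, 2, 3, 1, 3, 1, 4, 2, 5, 5, 6), directed = FALSE)
}
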
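# Exhaustive ensemble of nonisomorphic connected simple undirected graphs.
#
# The enumeration proceeds by vertex extension: every graph on n nodes
# contains a graph on n-1 nodes (delete any vertex), so attaching a new
# vertex to every subset of an exhaustive set of (n-1)-node graphs and
# deduplicating by canonical form yields an exhaustive set on n nodes.
# Intermediate sets keep disconnected graphs; connectivity is filtered
# only at the requested size.

# session cache: canonical-keyed sets of all (not necessarily connected)
# nonisomorphic graphs per size
.graphspace_cache <- new.env(parent = emptyenv())

#' Canonical form of a graph
#'
#' Returns a canonical label string such that two graphs receive the
#' same label if and only if they are isomorphic.  The label is the
#' graph6 encoding of the canonically relabelled graph (BLISS canonical
#' permutation), so it doubles as a portable, stable graph identifier.
#'
#' @param g an `igraph` object (undirected, simple).
#' @return a character string.
#' @examples
#' canonical_form(igraph::make_ring(3))
#' @export
canonical_form <- function(g) {
  stopifnot(igraph::is_igraph(g))
  perm <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, perm)
  graph6_encode(gc)
}

# internal: exhaustive set of ALL nonisomorphic simple graphs on n nodes,
# as a named list (name = canonical graph6 label)
all_nonisomorphic_graphs <- function(n) {
  key <- as.character(n)
  if (!is.null(.graphspace_cache[[key]])) return(.graphspace_cache[[key]])
  if (n == 1L) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    out <- stats::setNames(list(g), canonical_form(g))
  } else {
    parents <- all_nonisomorphic_graphs(n - 1L)
    out <- new.env(parent = emptyenv())
    nb_subsets <- lapply(0:(2^(n - 1L) - 1L), function(mask) {
      which(bitwAnd(bitwShiftR(mask, 0:(n - 2L)), 1L) == 1L)
    })
    for (p in parents) {
      pel <- igraph::as_edgelist(p, names = FALSE)
      for (nb in nb_subsets) {
        el <- rbind(pel, cbind(nb, rep.int(n, length(nb))))
        g <- igraph::make_empty_graph(n, directed = FALSE)
        if (nrow(el)) g <- igraph::add_edges(g, as.vector(t(el)))
        lab <- canonical_form(g)
        if (is.null(out[[lab]])) out[[lab]] <- g
      }
    }
    out <- as.list(out)
  }
  .graphspace_cache[[key]] <- out
  out
}

#' Enumerate all nonisomorphic connected graphs of a given size
#'
#' Generates exactly one representative per isomorphism class of the
#' connected simple undirected graphs on `n` nodes, in a deterministic
#' order (sorted by canonical label).  Each returned graph carries its
#' canonical label as the graph attribute `graph_id`.  In-process
#' enumeration is intended for n <= 8 (11117 classes); larger ensembles
#' should be generated externally (e.g. with geng) and imported through
#' [read_graph6()].
#'
#' @param n number of nodes, between 2 and 10.
#' @return named list of `igraph` objects; names are canonical labels.
#' @examples
#' length(enumerate_connected_graphs(4)) # 6
#' @export
enumerate_connected_graphs <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 2 || n > 10)
    stop("n must be a single integer between 2 and 10")
  n <- as.integer(n)
  all <- all_nonisomorphic_graphs(n)
  conn <- Filter(igraph::is_connected, all)
  ids <- names(conn)
  conn <- conn[order(ids, method = "radix")]
  for (i in seq_along(conn)) {
    conn[[i]] <- igraph::set_graph_attr(conn[[i]], "graph_id", names(conn)[i])
  }
  conn
}

# internal accessor: canonical id of a graph, cached as an attribute by
# the enumerator, computed on the fly otherwise
graph_id <- function(g) {
  id <- igraph::graph_attr(g, "graph_id")
  if (is.null(id)) canonical_form(g) else id
}

#' Automorphism orbits of the nodes of a graph
#'
#' Partitions the nodes into equivalence classes under the full
#' automorphism group.  Nodes in one orbit are structurally
#' interchangeable: they have identical centrality values and identical
#' expected outbreak sizes when used as epidemic seeds, which is what
#' makes the orbit partition useful for deduplicating exact solver runs.
#'
#' Orbits are the connected components of the relation i ~ s(i) taken
#' over a generating set s of the automorphism group.
#'
#' @param g an `igraph` object.
#' @return an object of class `orbit_partition`: a list with elements
#'   `graph_id`, `membership` (integer vector, orbit index per node) and
#'   `orbits` (list of integer vectors).
#' @examples
#' node_orbits(igraph::make_star(4, mode = "undirected"))
#' @export
node_orbits <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  gens <- igraph::automorphism_group(g)
  if (length(gens) == 0L) {
    membership <- seq_len(n)
  } else {
    edges <- unlist(lapply(gens, function(p) rbind(seq_len(n), as.integer(p))))
    rel <- igraph::make_graph(edges, n = n, directed = FALSE)
    membership <- igraph::components(rel)$membership
  }
  membership <- as.integer(match(membership, unique(membership)))
  structure(
    list(graph_id = graph_id(g),
         membership = membership,
         orbits = unname(split(seq_len(n), membership))),
    class = "orbit_partition")
}

#' @export
print.orbit_partition <- function(x, ...) {
  cat("orbit partition of graph", x$graph_id, "-", length(x$orbits), "orbit(s)\n")
  for (o in x$orbits) cat(" {", paste(o, collapse = " "), "}\n")
  invisible(x)
}

#' Distribution of edge counts across an ensemble
#'
#' Tabulates the number of edges M over a collection of graphs of one
#' common size N.  Connected simple graphs satisfy
#' N - 1 <= M <= N(N-1)/2, so all mass lies in that window.
#'
#' @param graphs list of `igraph` objects, all with the same node count.
#' @return named integer vector mapping M to the number of graphs.
#' @export
edge_count_distribution <- function(graphs) {
  stopifnot(length(graphs) > 0)
  ns <- vapply(graphs, function(g) as.integer(igraph::vcount(g)), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all graphs must have the same number of nodes")
  ms <- vapply(graphs, igraph::gsize, numeric(1))
  tab <- table(factor(ms, levels = sort(unique(ms))))
  stats::setNames(as.integer(tab), names(tab))
}
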
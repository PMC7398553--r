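# Independent brute-force oracles.  These deliberately avoid the code
# paths they validate: enumeration is checked against exhaustive labeled
# generation with VF2 isomorphism dedup (not canonical labeling), and
# orbits against exhaustive permutation search.

# Exhaustive labeled enumeration: all 2^C(n,2) labeled graphs, filter
# connected, deduplicate with pairwise VF2 isomorphism checks (bucketed
# by degree sequence).  Returns one igraph representative per class.
oracle_connected_classes <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  buckets <- new.env(parent = emptyenv())
  n_classes <- 0L
  reps <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    if (sum(sel) < n - 1L) next # too few edges to connect
    el <- pairs[, sel, drop = FALSE]
    # plain-R BFS connectivity
    adj <- vector("list", n)
    for (k in seq_len(ncol(el))) {
      a <- el[1L, k]; b <- el[2L, k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) next
    g <- igraph::make_graph(as.vector(el), n = n, directed = FALSE)
    key <- paste(sort(vapply(adj, length, integer(1))), collapse = ",")
    found <- FALSE
    for (r in buckets[[key]]) {
      if (igraph::is_isomorphic_to(g, reps[[r]], method = "vf2")) {
        found <- TRUE; break
      }
    }
    if (!found) {
      n_classes <- n_classes + 1L
      reps[[n_classes]] <- g
      buckets[[key]] <- c(buckets[[key]], n_classes)
    }
  }
  reps
}

# Exhaustive orbit oracle: test all n! vertex permutations for
# adjacency preservation, then merge nodes connected by any
# automorphism.
oracle_orbits <- function(g) {
  n <- as.integer(igraph::vcount(g))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  perms <- all_permutations(n)
  membership <- seq_len(n)
  find <- function(i) { while (membership[i] != i) i <- membership[i]; i }
  for (p in perms) {
    if (all(A[p, p] == A)) {
      for (i in seq_len(n)) {
        ri <- find(i); rj <- find(p[i])
        if (ri != rj) membership[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# count of automorphisms, by the same exhaustive search
oracle_automorphism_count <- function(g) {
  n <- as.integer(igraph::vcount(g))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  sum(vapply(all_permutations(n), function(p) all(A[p, p] == A), logical(1)))
}

# uniformly random relabeling of a graph
shuffle_graph <- function(g) {
  n <- igraph::vcount(g)
  igraph::permute(g, sample(n))
}

# canonical text form of an orbit partition, for comparisons
norm_orbits <- function(orbs) {
  sort(vapply(orbs, function(o) paste(sort(o), collapse = ","), character(1)))
}
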
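# Exact expected SIR outbreak size by configuration-tree unfolding.
#
# The outbreak state on a graph is a configuration: one of {S, I, R} per
# node.  With recovery rate fixed at 1 (time measured in units of the
# mean infectious period) the embedded jump chain moves from a
# configuration with M_SI susceptible-infectious edges and N_I
# infectious nodes by
#   - infecting across one specific SI edge  w.p. beta / (beta*M_SI + N_I)
#   - recovering one specific infectious node w.p.   1 / (beta*M_SI + N_I)
# The tree of configurations rooted at the seed is unfolded breadth
# first; identical configurations reached along different paths are
# merged by summing their probability mass (the process is Markovian, so
# the subtree below a configuration does not depend on the path to it).
# The expected outbreak size Omega is the mean number of ever-infected
# (= finally recovered) nodes over the absorbing configurations.
#
# Every configuration reachable after k events satisfies
# k = (N_I + N_R - 1) + N_R  (infections so far + recoveries so far),
# so identical configurations always meet at the same BFS depth and the
# per-depth hash map suffices for exhaustive merging.  All betas are
# propagated through a single traversal as a per-configuration mass
# vector.

#' Default transmission-rate grid
#'
#' Nine values in a geometric sequence with common ratio 2, from 1/16 to
#' 16, the grid used throughout the ensemble analyses.
#' @return numeric vector of length 9.
#' @export
beta_grid <- function() 2^(-4:4)

#' SIR model parameters
#'
#' The recovery rate is fixed at 1 (it sets the unit of time), so the
#' model is parameterized by the transmission rates beta alone.
#'
#' @param betas strictly increasing vector of positive transmission
#'   rates; default [beta_grid()].
#' @return object of class `sir_parameters`.
#' @export
sir_parameters <- function(betas = beta_grid()) {
  stopifnot(is.numeric(betas), length(betas) >= 1, all(betas > 0),
            all(diff(betas) > 0))
  structure(list(betas = as.numeric(betas), nu = 1), class = "sir_parameters")
}

as_betas <- function(params) {
  if (inherits(params, "sir_parameters")) params$betas
  else sir_parameters(params)$betas
}

# state encoding: integer vector, 0 = S, 1 = I, 2 = R
state_key <- function(s) rawToChar(as.raw(s + 83L)) # "S" = 83, maps 0->S,1->T,2->U

# per-beta labels, formatted one value at a time so "1" stays "1"
# whatever else is on the grid
beta_label <- function(betas) {
  vapply(betas, function(b) format(b, trim = TRUE), character(1))
}

#' One-step successor distribution of a configuration
#'
#' Expands a configuration into its immediate successors under the
#' embedded jump chain: one successor per susceptible-infectious edge
#' (that edge's susceptible endpoint becomes infectious) and one per
#' infectious node (that node recovers).  The probabilities sum to one;
#' the total infection probability is beta*M_SI / (beta*M_SI + N_I) and
#' the total recovery probability N_I / (beta*M_SI + N_I).
#'
#' @param state integer vector over \{0 = S, 1 = I, 2 = R\}, one entry
#'   per node.
#' @param g an `igraph` object.
#' @param beta single transmission rate.
#' @return data frame with columns `event` ("infection"/"recovery"),
#'   `node` (the node changing state), `prob`, and a list column
#'   `state` holding each successor configuration.
#' @export
successor_distribution <- function(state, g, beta) {
  stopifnot(length(state) == igraph::vcount(g), all(state %in% 0:2),
            is.numeric(beta), length(beta) == 1, beta > 0)
  state <- as.integer(state)
  el <- igraph::as_edgelist(g, names = FALSE)
  n_i <- sum(state == 1L)
  if (n_i == 0L)
    stop("absorbing configuration (no infectious node) has no successors")
  s1 <- state[el[, 1L]]; s2 <- state[el[, 2L]]
  si <- which((s1 == 0L & s2 == 1L) | (s1 == 1L & s2 == 0L))
  m_si <- length(si)
  denom <- beta * m_si + n_i
  succ_states <- vector("list", m_si + n_i)
  event <- character(m_si + n_i)
  node <- integer(m_si + n_i)
  prob <- numeric(m_si + n_i)
  k <- 0L
  for (e in si) {
    v <- if (state[el[e, 1L]] == 0L) el[e, 1L] else el[e, 2L]
    s2v <- state; s2v[v] <- 1L
    k <- k + 1L
    succ_states[[k]] <- s2v; event[k] <- "infection"; node[k] <- v
    prob[k] <- beta / denom
  }
  for (v in which(state == 1L)) {
    s2v <- state; s2v[v] <- 2L
    k <- k + 1L
    succ_states[[k]] <- s2v; event[k] <- "recovery"; node[k] <- v
    prob[k] <- 1 / denom
  }
  out <- data.frame(event = event, node = node, prob = prob)
  out$state <- succ_states
  out
}

#' Exact expected outbreak size for one seed node
#'
#' Unfolds the complete configuration tree of the Markovian SIR model
#' started from a single infectious seed, breadth first with merging of
#' identical configurations, and returns the exact expected number of
#' ever-infected nodes Omega for every requested transmission rate.
#' All rates are handled in one traversal: each configuration carries a
#' per-beta probability mass vector.
#'
#' @param g a connected `igraph` object.
#' @param seed seed node index (1-based).
#' @param params an [sir_parameters()] object or a numeric beta vector.
#' @param diagnostics if `TRUE`, attach per-depth probability-mass
#'   bookkeeping (active + absorbed mass per beta at every BFS depth) as
#'   attribute `"conservation"`.
#' @return named numeric vector: Omega per beta.
#' @examples
#' expected_outbreak_size(igraph::make_full_graph(2), 1, 1)  # 1.5
#' @export
expected_outbreak_size <- function(g, seed, params = sir_parameters(),
                                   diagnostics = FALSE) {
  stopifnot(igraph::is_igraph(g))
  n <- as.integer(igraph::vcount(g))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, seed >= 1L, seed <= n)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  betas <- as_betas(params)
  nb <- length(betas)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  e1 <- el[, 1L]; e2 <- el[, 2L]

  s0 <- integer(n); s0[seed] <- 1L
  frontier <- new.env(hash = TRUE, parent = emptyenv())
  assign(state_key(s0), list(s = s0, mass = rep(1, nb)), envir = frontier)
  omega <- numeric(nb)
  absorbed <- numeric(nb)
  conservation <- if (diagnostics) list() else NULL
  depth <- 0L

  while (length(ls(frontier)) > 0L) {
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(frontier)) {
      cfg <- frontier[[key]]
      s <- cfg$s
      mass <- cfg$mass
      n_i <- sum(s == 1L)
      # exhaustive BFS invariant: event count determines the state census
      stopifnot(depth == n_i + 2L * sum(s == 2L) - 1L)
      s1 <- s[e1]; s2 <- s[e2]
      si <- which((s1 == 0L & s2 == 1L) | (s1 == 1L & s2 == 0L))
      m_si <- length(si)
      denom <- betas * m_si + n_i
      p_inf <- betas / denom
      p_rec <- 1 / denom
      for (e in si) {
        v <- if (s[e1[e]] == 0L) e1[e] else e2[e]
        sv <- s; sv[v] <- 1L
        k <- state_key(sv)
        prev <- nxt[[k]]
        if (is.null(prev)) nxt[[k]] <- list(s = sv, mass = mass * p_inf)
        else nxt[[k]] <- list(s = sv, mass = prev$mass + mass * p_inf)
      }
      for (v in which(s == 1L)) {
        sv <- s; sv[v] <- 2L
        if (n_i == 1L) {
          # last infectious node recovered: absorbing, accumulate now
          m <- mass * p_rec
          omega <- omega + m * sum(sv == 2L)
          absorbed <- absorbed + m
        } else {
          k <- state_key(sv)
          prev <- nxt[[k]]
          if (is.null(prev)) nxt[[k]] <- list(s = sv, mass = mass * p_rec)
          else nxt[[k]] <- list(s = sv, mass = prev$mass + mass * p_rec)
        }
      }
    }
    depth <- depth + 1L
    if (diagnostics) {
      active <- rep(0, nb)
      for (key in ls(nxt)) active <- active + nxt[[key]]$mass
      conservation[[depth]] <- data.frame(depth = depth, beta = betas,
                                          active = active, absorbed = absorbed,
                                          total = active + absorbed)
    }
    frontier <- nxt
  }
  res <- stats::setNames(omega, beta_label(betas))
  if (diagnostics)
    attr(res, "conservation") <- do.call(rbind, conservation)
  res
}

#' Exact outbreak sizes for every seed node of a graph
#'
#' Runs the exact solver once per automorphism orbit (structurally
#' equivalent seeds give identical outbreak sizes) and replicates the
#' result to all orbit members, producing the long-format table indexed
#' by (graph, seed, beta).
#'
#' @param g a connected `igraph` object.
#' @param params an [sir_parameters()] object or numeric beta vector.
#' @param orbits optional precomputed [node_orbits()] partition for `g`.
#' @return data frame with columns `graph_id`, `seed`, `beta`, `omega`;
#'   N x length(betas) rows, ordered by seed then beta.
#' @export
outbreak_table <- function(g, params = sir_parameters(), orbits = NULL) {
  n <- as.integer(igraph::vcount(g))
  betas <- as_betas(params)
  if (is.null(orbits)) orbits <- node_orbits(g)
  stopifnot(inherits(orbits, "orbit_partition"))
  if (length(orbits$membership) != n ||
      !setequal(unlist(orbits$orbits), seq_len(n)))
    stop("orbit partition does not match the graph")
  id <- graph_id(g)
  if (orbits$graph_id != id)
    stop("orbit partition belongs to a different graph")
  omega_by_node <- matrix(NA_real_, nrow = n, ncol = length(betas))
  for (orb in orbits$orbits) {
    om <- expected_outbreak_size(g, orb[1L], betas)
    omega_by_node[orb, ] <- matrix(om, nrow = length(orb),
                                   ncol = length(betas), byrow = TRUE)
  }
  data.frame(graph_id = id,
             seed = rep(seq_len(n), each = length(betas)),
             beta = rep(betas, times = n),
             omega = as.vector(t(omega_by_node)))
}

#' Exact outbreak sizes for a whole ensemble
#'
#' Applies [outbreak_table()] to every graph in a collection, in order.
#'
#' @param graphs list of connected `igraph` objects (typically from
#'   [enumerate_connected_graphs()] or [read_graph6()]).
#' @param params an [sir_parameters()] object or numeric beta vector.
#' @return row-bound data frame of [outbreak_table()] results.
#' @export
solve_graphs <- function(graphs, params = sir_parameters()) {
  do.call(rbind, lapply(graphs, outbreak_table, params = params))
}
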
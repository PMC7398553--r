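# Independent validation oracles for the exact solver.
#
# markov_oracle() takes a completely different computational route: it
# builds the full 3^N-state absorbing Markov chain over configurations
# and obtains the expected number of recovered nodes at absorption by a
# single sparse linear solve (no tree unfolding, no merging).
# gillespie_estimate() is the stochastic route: event-driven Monte Carlo
# with the same event rates.

#' Absorbing-Markov-chain oracle for the expected outbreak size
#'
#' Enumerates all 3^N configurations, assembles the jump-chain
#' transition matrix, and solves (I - Q) h = b for the expected number
#' of recovered nodes at absorption, where Q is the transient-to-
#' transient block.  Exact up to linear-algebra round-off; intended as a
#' cross-check of [expected_outbreak_size()] on small graphs.
#'
#' @param g connected `igraph` object with at most 6 nodes.
#' @param seed seed node index.
#' @param beta single transmission rate.
#' @return the expected outbreak size (scalar).
#' @export
markov_oracle <- function(g, seed, beta) {
  n <- as.integer(igraph::vcount(g))
  if (n > 6L) stop("markov_oracle is limited to graphs of at most 6 nodes")
  stopifnot(length(beta) == 1, beta > 0)
  seed <- as.integer(seed)
  stopifnot(seed >= 1L, seed <= n)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"

  nstates <- 3L^n
  pow <- 3L^(0:(n - 1L))
  # decode all states at once: states[k, v] in {0,1,2}
  states <- sapply(seq_len(n), function(v) ((seq_len(nstates) - 1L) %/% pow[v]) %% 3L)
  n_i <- rowSums(states == 1L)
  n_r <- rowSums(states == 2L)
  transient <- which(n_i > 0L)
  tindex <- integer(nstates); tindex[transient] <- seq_along(transient)

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  b <- numeric(length(transient))
  for (t in seq_along(transient)) {
    k <- transient[t]
    s <- states[k, ]
    s1 <- s[el[, 1L]]; s2 <- s[el[, 2L]]
    si <- which((s1 == 0L & s2 == 1L) | (s1 == 1L & s2 == 0L))
    denom <- beta * length(si) + n_i[k]
    for (e in si) {
      v <- if (s[el[e, 1L]] == 0L) el[e, 1L] else el[e, 2L]
      k2 <- k + pow[v] # S(0) -> I(1)
      ti <- c(ti, t); tj <- c(tj, tindex[k2]); tx <- c(tx, beta / denom)
    }
    for (v in which(s == 1L)) {
      k2 <- k + pow[v] # I(1) -> R(2)
      p <- 1 / denom
      if (n_i[k2] == 0L) b[t] <- b[t] + p * n_r[k2]
      else { ti <- c(ti, t); tj <- c(tj, tindex[k2]); tx <- c(tx, p) }
    }
  }
  nt <- length(transient)
  Q <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(nt, nt))
  h <- Matrix::solve(Matrix::Diagonal(nt) - Q, b)
  start <- 1L + pow[seed] # seed infectious, everyone else susceptible
  as.numeric(h[tindex[start]])
}

#' Monte-Carlo estimate of the expected outbreak size
#'
#' Event-driven Gillespie simulation of the Markovian SIR model (jump
#' chain with the same per-event probabilities as the exact solver),
#' returning the sample mean final outbreak size and its standard
#' error over `n_runs` independent outbreaks.  Uses R's RNG stream, so
#' results are reproducible under `set.seed()` via `rng_seed`.
#'
#' @param g connected `igraph` object.
#' @param seed seed node index.
#' @param beta single transmission rate.
#' @param n_runs number of independent outbreaks (>= 1).
#' @param rng_seed integer seed for the RNG.
#' @return list with `mean`, `se`, and `n_runs`.
#' @export
gillespie_estimate <- function(g, seed, beta, n_runs = 1e5, rng_seed = 1L) {
  n <- as.integer(igraph::vcount(g))
  seed <- as.integer(seed)
  stopifnot(seed >= 1L, seed <= n, n_runs >= 1, beta >= 0)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  set.seed(as.integer(rng_seed))
  sizes <- gillespie_runs_cpp(n, el, seed, beta, as.integer(n_runs))
  list(mean = mean(sizes),
       se = stats::sd(sizes) / sqrt(length(sizes)),
       n_runs = as.integer(n_runs))
}
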
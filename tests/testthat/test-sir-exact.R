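test_that("successor distribution reproduces the jump-chain probabilities", {
  tri <- igraph::make_full_graph(3)
  # seed infectious, two susceptible neighbors: M_SI = 2, N_I = 1
  succ <- successor_distribution(c(1, 0, 0), tri, beta = 1)
  expect_equal(sum(succ$prob), 1)
  expect_equal(sum(succ$prob[succ$event == "infection"]), 2 / 3)
  expect_equal(sum(succ$prob[succ$event == "recovery"]), 1 / 3)

  # two infectious nodes, no SI edge: two recoveries at 1/2 each
  p3 <- path_graph(3)
  succ <- successor_distribution(c(1, 2, 1), p3, beta = 4)
  expect_equal(nrow(succ), 2)
  expect_true(all(succ$event == "recovery"))
  expect_equal(succ$prob, c(1 / 2, 1 / 2))

  # single edge, IS, beta = 3: infect 3/4, recover 1/4
  edge <- igraph::make_full_graph(2)
  succ <- successor_distribution(c(1, 0), edge, beta = 3)
  expect_equal(succ$prob[succ$event == "infection"], 3 / 4)
  expect_equal(succ$prob[succ$event == "recovery"], 1 / 4)

  # absorbing configurations have no successors
  expect_error(successor_distribution(c(2, 0, 0), p3, beta = 1), "absorbing")
})

test_that("closed forms: single edge and triangle", {
  b <- beta_grid()
  om <- expected_outbreak_size(igraph::make_full_graph(2), 1, b)
  expect_equal(unname(om), 1 + b / (b + 1), tolerance = 1e-14)

  om_tri <- expected_outbreak_size(igraph::make_full_graph(3), 1, 1)
  expect_equal(unname(om_tri), 13 / 6, tolerance = 1e-14)
})

test_that("vanishing transmission rate gives outbreak size 1", {
  for (g in list(path_graph(4), igraph::make_full_graph(5))) {
    om <- expected_outbreak_size(g, 1, 1e-9)
    expect_equal(unname(om), 1, tolerance = 1e-6)
  }
})

test_that("exact solver matches the absorbing-Markov oracle on assorted graphs", {
  graphs <- list(igraph::make_full_graph(2), igraph::make_full_graph(3),
                 path_graph(4), igraph::make_star(5, mode = "undirected"),
                 triangle_pendant_graph())
  for (g in graphs) {
    for (beta in c(1 / 4, 1, 4)) {
      om <- expected_outbreak_size(g, 1, beta)
      expect_equal(unname(om), markov_oracle(g, 1, beta), tolerance = 1e-12)
    }
  }
})

test_that("markov oracle approaches N for large beta on a path end seed", {
  om <- markov_oracle(path_graph(3), 1, 1e6)
  expect_equal(om, 3, tolerance = 1e-4)
  expect_error(markov_oracle(path_graph(7), 1, 1), "at most 6")
})

test_that("probability mass is conserved at every BFS depth", {
  set.seed(7)
  for (g in ensemble6()[sample(112, 8)]) {
    om <- expected_outbreak_size(g, 1, beta_grid(), diagnostics = TRUE)
    cons <- attr(om, "conservation")
    expect_true(all(abs(cons$total - 1) < 1e-12))
  }
})

test_that("outbreak size grows with beta and stays within [1, N]", {
  tab <- fixture("tab6_sample", {
    set.seed(11)
    do.call(rbind, lapply(ensemble6()[sample(112, 10)], outbreak_table))
  })
  expect_true(all(tab$omega >= 1 & tab$omega <= 6))
  for (d in split(tab, paste(tab$graph_id, tab$seed))) {
    d <- d[order(d$beta), ]
    expect_true(all(diff(d$omega) > 0)) # every node has a neighbor here
  }
})

test_that("automorphically equivalent seeds give identical outbreak sizes", {
  set.seed(3)
  for (g in ensemble6()[sample(112, 6)]) {
    orb <- node_orbits(g)
    multi <- Filter(function(o) length(o) >= 2, orb$orbits)
    for (o in multi) {
      # computed independently, not copied via the orbit shortcut
      om1 <- expected_outbreak_size(g, o[1], c(1 / 2, 2))
      om2 <- expected_outbreak_size(g, o[2], c(1 / 2, 2))
      expect_equal(om1, om2, tolerance = 1e-12)
    }
  }
})

test_that("outbreak_table solves once per orbit and fills all seeds", {
  tri <- igraph::make_full_graph(3)
  tab <- outbreak_table(tri)
  expect_equal(nrow(tab), 3 * 9)
  expect_equal(length(unique(tab$omega[tab$beta == 1])), 1)

  star <- igraph::make_star(4, mode = "undirected")
  tab <- outbreak_table(star)
  expect_equal(nrow(tab), 4 * 9)
  center <- tab[tab$seed == 1, ]
  leaf <- tab[tab$seed == 2, ]
  expect_true(all(center$omega > leaf$omega))

  # an orbit partition from a different graph is rejected
  expect_error(outbreak_table(star, orbits = node_orbits(tri)),
               "different graph|does not match")
})

test_that("solver is consistent with the Gillespie oracle", {
  # beta = 0: the seed always recovers before infecting anyone
  ge0 <- gillespie_estimate(path_graph(3), 1, 0, n_runs = 500, rng_seed = 5)
  expect_equal(ge0$mean, 1)
  expect_equal(ge0$se, 0)

  ge <- gillespie_estimate(igraph::make_full_graph(2), 1, 1,
                           n_runs = 1e5, rng_seed = 1)
  expect_lt(abs(ge$mean - 1.5), 3 * ge$se)

  ge <- gillespie_estimate(igraph::make_full_graph(3), 1, 1,
                           n_runs = 1e5, rng_seed = 2)
  expect_lt(abs(ge$mean - 13 / 6), 3 * ge$se)
})

test_that("solver agrees with Gillespie on random (graph, seed, beta) triples", {
  set.seed(19)
  ens <- ensemble6()
  misses <- 0L
  for (i in 1:20) {
    g <- ens[[sample(112, 1)]]
    seed <- sample(6, 1)
    beta <- sample(beta_grid(), 1)
    om <- unname(expected_outbreak_size(g, seed, beta))
    ge <- gillespie_estimate(g, seed, beta, n_runs = 1e5,
                             rng_seed = 1000 + i)
    if (abs(ge$mean - om) >= 3 * ge$se) misses <- misses + 1L
  }
  # each triple is inside 3 SE with probability ~0.997; allow one excursion
  expect_lte(misses, 1L)
})

test_that("sir parameter validation and solver preconditions hold", {
  expect_error(sir_parameters(c(1, 1)), "")
  expect_error(sir_parameters(c(-1, 1)), "")
  expect_error(expected_outbreak_size(igraph::make_empty_graph(3, directed = FALSE), 1, 1),
               "connected")
  expect_error(expected_outbreak_size(path_graph(3), 5, 1), "")
})
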
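# a small synthetic view builder: y = f(x) + noise over a unit-interval
# feature, wrapped with the attributes run_experiment() expects
synthetic_view <- function(n, noise_sd = 0, seed = 1, f = identity) {
  set.seed(seed)
  x <- runif(n)
  df <- data.frame(degree = x, omega = f(x) + rnorm(n, sd = noise_sd))
  structure(df, beta = 1, features = "degree",
            class = c("experiment_view", "data.frame"))
}

fast_config <- function(regressor = "forest") {
  # single-point grid keeps simulation-heavy tests quick
  regression_config(regressor, trees = 20L, leaf_fractions = 1e-2,
                    costs = 1, kernels = "radial", folds = 5L)
}

test_that("r_squared implements 1 - S_res/S_tot", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(10, -4, 7)), -10) # unbounded below
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "")
})

test_that("a learnable identity target is recovered almost perfectly", {
  v <- synthetic_view(400)
  res <- run_experiment(v, regression_config("svm", kernels = "linear",
                                             costs = c(1, 100)),
                        seed = 2)
  expect_gt(res$r2_test, 0.999)
})

test_that("independent (permuted) targets score near zero", {
  v <- synthetic_view(10000, seed = 3)
  v$omega <- sample(v$omega) # destroy the dependence
  res <- run_experiment(v, fast_config(), seed = 4)
  # forests with small leaves carry a slight negative bias on pure
  # noise; near zero (and never positive signal) is what matters
  expect_lt(res$r2_test, 0.03)
  expect_gt(res$r2_test, -0.15)
})

test_that("dev and test rows are disjoint and the split is seed-reproducible", {
  v <- project_and_dedup(records6(), c("degree", "closeness"), 1)
  res1 <- run_experiment(v, fast_config(), seed = 10)
  res2 <- run_experiment(v, fast_config(), seed = 10)
  expect_identical(res1$dev_rows, res2$dev_rows)
  expect_identical(res1$r2_test, res2$r2_test) # forest path is bit-identical
  expect_length(intersect(res1$dev_rows, setdiff(seq_len(nrow(v)), res1$dev_rows)), 0)
  expect_equal(res1$dev_size, floor(0.75 * nrow(v)))

  res3 <- run_experiment(v, fast_config(), seed = 11)
  expect_false(identical(res1$dev_rows, res3$dev_rows))
})

test_that("svm experiments are reproducible to numerical tolerance", {
  v <- project_and_dedup(records6(), c("degree", "pagerank"), 1)
  res1 <- run_experiment(v, fast_config("svm"), seed = 5)
  res2 <- run_experiment(v, fast_config("svm"), seed = 5)
  expect_equal(res1$r2_test, res2$r2_test, tolerance = 1e-10)
})

test_that("both regressor kinds score similarly on the same views", {
  # compared on the strongest two-feature combination, where both
  # models have enough signal for their scores to be stable
  for (beta in c(1 / 4, 1, 4)) {
    v <- project_and_dedup(records6(), c("density", "katz"), beta)
    rf <- run_experiment(v, regression_config("forest"), seed = 6)
    sv <- run_experiment(v, regression_config("svm"), seed = 6)
    expect_lt(abs(rf$r2_test - sv$r2_test), 0.05)
  }
})

test_that("degenerate views are rejected", {
  v <- synthetic_view(15)
  expect_error(run_experiment(v, fast_config()), "at least 21")
})

test_that("the learning curve plateaus on an easy synthetic problem", {
  v <- synthetic_view(1000, noise_sd = 0.05, seed = 8)
  tuned <- tune_dev_size(v, fast_config(), seed = 8)
  expect_true(tuned$converged)
  expect_lt(tuned$size, max(tuned$curve$size)) # well below the maximum
  expect_equal(nrow(tuned$curve), 10)
  expect_true(all(diff(tuned$curve$size) > 0))

  expect_error(tune_dev_size(synthetic_view(40), fast_config()),
               "too small")
})

test_that("development fraction chosen for the small-ensemble data is large", {
  v <- project_and_dedup(records6(), c("degree", "pagerank"), 1)
  tuned <- tune_dev_size(v, regression_config("forest"), seed = 9)
  expect_gte(tuned$fraction, 0.5)
})

test_that("permutation p-values hit the minimum under real dependence", {
  v <- project_and_dedup(records6(), c("degree", "pagerank"), 1)
  pt <- permutation_test(v, fast_config(), n_permutations = 30, seed = 12)
  expect_equal(pt$p_value, 1 / 31)
  expect_length(pt$permuted_scores, 30)
  expect_gt(pt$score, max(pt$permuted_scores))
})

test_that("permutation p-value estimator has the add-one form", {
  # with a deterministic signal and one permutation the permuted score
  # loses, so p = (1 + 0) / (1 + 1)
  v <- synthetic_view(200)
  pt <- permutation_test(v, fast_config(), n_permutations = 1, seed = 13)
  expect_equal(pt$p_value, 0.5)
  expect_error(permutation_test(v, fast_config(), n_permutations = 0), ">= 1")
})

test_that("sweeps cover the grid and summarize the minimum over beta", {
  rec <- records6()
  sw <- sweep_experiments(rec, list("degree", c("degree", "katz")),
                          betas = c(1 / 16, 1, 16),
                          config = fast_config(), seed = 20)
  expect_equal(nrow(sw), 6)
  expect_setequal(unique(sw$combo), c("degree", "degree+katz"))
  smry <- sweep_summary(sw)
  expect_equal(nrow(smry), 2)
  for (cb in smry$combo) {
    expect_equal(smry$min_r2[smry$combo == cb],
                 min(sw$r2_test[sw$combo == cb]))
  }

  # identical seeds give identical sweeps (forest path)
  sw2 <- sweep_experiments(rec, list("degree", c("degree", "katz")),
                           betas = c(1 / 16, 1, 16),
                           config = fast_config(), seed = 20)
  expect_identical(sw$r2_test, sw2$r2_test)
})

test_that("sweep records degenerate cells as missing instead of failing", {
  ens4 <- enumerate_connected_graphs(4)
  rec4 <- assemble_records(featurize(ens4), solve_graphs(ens4))
  expect_warning(
    sw <- sweep_experiments(rec4, list("degree"), betas = 1,
                            config = fast_config(), seed = 1),
    "skipped")
  expect_true(is.na(sw$r2_test[1]))
})
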
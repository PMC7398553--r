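# Regression protocol measuring how well centrality features predict
# the exact outbreak size.
#
# For one (graph size, beta, feature combination) cell: deduplicated
# records are split into development and test data; hyperparameters are
# grid-searched with ten-fold cross-validation on the development part;
# the best model is refit on all development data and scored on the
# held-out test data with the coefficient of determination R^2.
# Significance is assessed with a permutation test: the cross-validated
# score of the real data is compared against scores obtained after
# randomly permuting the target.

#' Coefficient of determination
#'
#' R^2 = 1 - S_res / S_tot, where S_res is the residual sum of squares
#' and S_tot the total sum of squares about the mean of the true
#' targets.  Perfect prediction gives 1, predicting the mean gives 0;
#' arbitrarily negative values are possible.
#'
#' @param truth numeric vector of true targets (non-constant).
#' @param estimate numeric vector of predictions, same length.
#' @return scalar R^2.
#' @export
r_squared <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) > 0)
  s_tot <- sum((truth - mean(truth))^2)
  if (s_tot == 0)
    stop("R^2 is undefined for constant true targets")
  1 - sum((truth - estimate)^2) / s_tot
}

#' Regression protocol configuration
#'
#' @param regressor "forest" (random forest) or "svm" (support vector
#'   regression).
#' @param trees forest grid: numbers of trees (kept small, <= 20).
#' @param leaf_fractions forest grid: minimum fraction of the training
#'   size required at a leaf (controls overfitting).
#' @param costs svm grid: regularization parameter C.
#' @param kernels svm grid: kernel types.
#' @param epsilon svm tube width (no training penalty within epsilon).
#' @param folds number of cross-validation folds.
#' @param dev_fraction fraction of rows used as development data when
#'   the development size is not tuned.
#' @param plateau_tol learning-curve plateau tolerance: a size counts as
#'   converged when validation R^2 is within this of its maximum.
#' @param gap_tol maximum allowed training-minus-validation gap for the
#'   learning curve to count as converged.
#' @return object of class `regression_config`.
#' @export
regression_config <- function(regressor = c("forest", "svm"),
                              trees = c(5L, 10L, 15L, 20L),
                              leaf_fractions = c(1e-2, 3e-3, 1e-3, 3e-4, 1e-4),
                              costs = c(0.1, 1, 10, 100),
                              kernels = c("linear", "radial"),
                              epsilon = 0.01,
                              folds = 10L,
                              dev_fraction = 0.75,
                              plateau_tol = 0.005,
                              gap_tol = 0.02) {
  regressor <- match.arg(regressor)
  stopifnot(folds >= 2, length(trees) >= 1, length(leaf_fractions) >= 1,
            length(costs) >= 1, all(kernels %in% c("linear", "radial")),
            dev_fraction > 0, dev_fraction < 1)
  structure(list(regressor = regressor, trees = sort(as.integer(trees)),
                 leaf_fractions = sort(leaf_fractions, decreasing = TRUE),
                 costs = sort(costs), kernels = kernels, epsilon = epsilon,
                 folds = as.integer(folds), dev_fraction = dev_fraction,
                 plateau_tol = plateau_tol, gap_tol = gap_tol),
            class = "regression_config")
}

# hyperparameter grid, ordered from simple to complex so that the first
# maximum of the validation score is the simplest adequate model
hyper_grid <- function(config) {
  if (config$regressor == "forest") {
    g <- expand.grid(leaf_fraction = config$leaf_fractions,
                     trees = config$trees)[, c("trees", "leaf_fraction")]
  } else {
    kernels <- intersect(c("linear", "radial"), config$kernels)
    g <- expand.grid(cost = config$costs, kernel = kernels,
                     stringsAsFactors = FALSE)[, c("kernel", "cost")]
  }
  g
}

# reference model for learning curves: heavier leaf smoothing than the
# tuning grid, so the in-sample training score is not inflated by
# memorization and the train/validation gap reflects data sufficiency
# rather than forest overfit
curve_hyper <- function(config) {
  if (config$regressor == "forest")
    list(trees = max(config$trees), leaf_fraction = 0.03)
  else
    list(kernel = "radial", cost = 1)
}

fit_model <- function(x, y, config, hyper) {
  if (config$regressor == "forest") {
    fit <- randomForest::randomForest(
      x = x, y = y, ntree = hyper$trees,
      nodesize = max(1L, ceiling(hyper$leaf_fraction * length(y))))
  } else {
    xm <- as.matrix(x)
    v <- stats::var(as.vector(xm))
    gamma <- if (v > 0) 1 / (ncol(xm) * v) else 1
    fit <- e1071::svm(x = xm, y = y, type = "eps-regression",
                      kernel = hyper$kernel, cost = hyper$cost,
                      gamma = gamma, epsilon = config$epsilon,
                      scale = FALSE)
  }
  structure(list(fit = fit, config = config, hyper = hyper,
                 features = colnames(x)),
            class = "sirpredict_model")
}

#' @export
predict.sirpredict_model <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  if (object$config$regressor == "svm") x <- as.matrix(x)
  as.numeric(stats::predict(object$fit, x))
}

# ten-fold CV of one hyperparameter setting; returns mean train and
# validation R^2 across folds.  Fold assignment is supplied so that the
# whole grid is compared on identical folds.
cv_score <- function(data, config, hyper, fold_id) {
  folds <- sort(unique(fold_id))
  train_r2 <- val_r2 <- numeric(length(folds))
  for (i in seq_along(folds)) {
    hold <- fold_id == folds[i]
    tr <- data[!hold, , drop = FALSE]
    ho <- data[hold, , drop = FALSE]
    m <- fit_model(tr[, setdiff(names(tr), "omega"), drop = FALSE],
                   tr$omega, config, hyper)
    train_r2[i] <- r_squared(tr$omega, predict(m, tr))
    val_r2[i] <- r_squared(ho$omega, predict(m, ho))
  }
  c(train = mean(train_r2), validation = mean(val_r2))
}

# grid search with ten-fold CV; returns best hyperparameters (first
# maximum in simple-to-complex order) and the score table
grid_search <- function(dev, config) {
  grid <- hyper_grid(config)
  fold_id <- sample(rep_len(seq_len(config$folds), nrow(dev)))
  scores <- t(vapply(seq_len(nrow(grid)), function(i) {
    cv_score(dev, config, as.list(grid[i, , drop = FALSE]), fold_id)
  }, c(train = 0, validation = 0)))
  best <- which.max(scores[, "validation"])
  list(hyper = as.list(grid[best, , drop = FALSE]),
       cv_validation_r2 = scores[best, "validation"],
       table = cbind(grid, scores))
}

#' Tune the development-data size with a learning curve
#'
#' Treats the size of the development data as a hyperparameter: ten
#' candidate sizes on a linear scale up to 90\% of the data are
#' cross-validated, and the chosen size is the smallest at which the
#' validation curve is close to the training curve (gap below
#' `gap_tol`) and has leveled off (within `plateau_tol` of its maximum
#' over the candidate sizes).  If no size qualifies, the maximum size is
#' returned with `converged = FALSE`.
#'
#' @param view an `experiment_view` from [project_and_dedup()].
#' @param config a [regression_config()].
#' @param seed integer seed.
#' @return list with `size`, `fraction`, `converged`, and `curve` (a
#'   data frame of sizes and mean training/validation R^2).
#' @export
tune_dev_size <- function(view, config = regression_config(), seed = 1L) {
  n <- nrow(view)
  max_size <- floor(0.9 * n)
  sizes <- unique(round(seq(max_size / 10, max_size, length.out = 10)))
  if (min(sizes) < 2 * config$folds)
    stop("view too small to trace a ten-point learning curve: ",
         "smallest candidate size ", min(sizes), " cannot support ",
         config$folds, "-fold cross-validation")
  set.seed(as.integer(seed))
  hyper <- curve_hyper(config)
  curve <- data.frame(size = sizes, train_r2 = NA_real_,
                      validation_r2 = NA_real_)
  for (i in seq_along(sizes)) {
    rows <- sample.int(n, sizes[i])
    sub <- view[rows, , drop = FALSE]
    fold_id <- sample(rep_len(seq_len(config$folds), nrow(sub)))
    sc <- cv_score(sub, config, hyper, fold_id)
    curve$train_r2[i] <- sc["train"]
    curve$validation_r2[i] <- sc["validation"]
  }
  ok <- curve$validation_r2 >= max(curve$validation_r2) - config$plateau_tol &
    (curve$train_r2 - curve$validation_r2) < config$gap_tol
  if (any(ok)) {
    size <- sizes[which(ok)[1L]]
    converged <- TRUE
  } else {
    size <- max(sizes)
    converged <- FALSE
    warning("learning curve did not converge; using the maximum size")
  }
  list(size = size, fraction = size / n, converged = converged, curve = curve)
}

#' Run one regression experiment
#'
#' Splits a deduplicated view into development and test data, tunes
#' hyperparameters by grid search with ten-fold cross-validation on the
#' development part, refits the best model on all development data, and
#' reports the test-set R^2.  Fully reproducible from the seed.
#'
#' @param view an `experiment_view` from [project_and_dedup()].
#' @param config a [regression_config()].
#' @param seed integer seed.
#' @param tune_dev if `TRUE`, the development size is chosen with
#'   [tune_dev_size()]; otherwise `config$dev_fraction` is used.
#' @return object of class `experiment_result`: a list with the view
#'   provenance, chosen development size, tuned hyperparameters,
#'   test R^2, and the fitted model.
#' @export
run_experiment <- function(view, config = regression_config(), seed = 1L,
                           tune_dev = FALSE) {
  n <- nrow(view)
  if (n <= 20)
    stop("view has ", n, " rows; at least 21 are required")
  feats <- attr(view, "features")
  if (tune_dev) {
    tuned <- tune_dev_size(view, config, seed = seed)
    dev_size <- tuned$size
  } else {
    tuned <- NULL
    dev_size <- floor(config$dev_fraction * n)
  }
  set.seed(as.integer(seed))
  dev_idx <- sample.int(n, dev_size)
  dev <- as.data.frame(view)[dev_idx, , drop = FALSE]
  test <- as.data.frame(view)[-dev_idx, , drop = FALSE]
  gs <- grid_search(dev, config)
  model <- fit_model(dev[, feats, drop = FALSE], dev$omega, config, gs$hyper)
  r2 <- r_squared(test$omega, predict(model, test))
  structure(list(beta = attr(view, "beta"), features = feats,
                 regressor = config$regressor, n_rows = n,
                 dev_size = dev_size, dev_fraction = dev_size / n,
                 hyper = gs$hyper, cv_validation_r2 = gs$cv_validation_r2,
                 r2_test = r2, seed = as.integer(seed),
                 dev_rows = sort(dev_idx),
                 learning_curve = tuned, model = model),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: omega(beta = %g) ~ %s [%s]\n", x$beta,
              paste(x$features, collapse = " + "), x$regressor))
  cat(sprintf("  rows %d, dev %d (%.0f%%), test R^2 = %.4f\n",
              x$n_rows, x$dev_size, 100 * x$dev_fraction, x$r2_test))
  hy <- paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  cat("  tuned:", hy, "\n")
  invisible(x)
}

#' Permutation test of feature-target dependence
#'
#' Compares the cross-validated score of the real data against scores
#' obtained after permuting the target, destroying any structural
#' dependence.  The p-value uses the add-one estimator
#' p = (1 + #\{permuted >= real\}) / (1 + n_permutations), whose
#' minimum attainable value is 1/(n_permutations + 1); a real
#' dependence therefore yields p = 1/101 at the default 100
#' permutations.
#'
#' @param view an `experiment_view` from [project_and_dedup()].
#' @param config a [regression_config()].
#' @param n_permutations number of target permutations (>= 1).
#' @param seed integer seed.
#' @return list with `p_value`, `score` (real cross-validated R^2) and
#'   `permuted_scores`.
#' @export
permutation_test <- function(view, config = regression_config(),
                             n_permutations = 100L, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  n <- nrow(view)
  if (n <= 20)
    stop("view has ", n, " rows; at least 21 are required")
  set.seed(as.integer(seed))
  dev_idx <- sample.int(n, floor(config$dev_fraction * n))
  dev <- as.data.frame(view)[dev_idx, , drop = FALSE]
  gs <- grid_search(dev, config)
  fold_id <- sample(rep_len(seq_len(config$folds), nrow(dev)))
  score <- cv_score(dev, config, gs$hyper, fold_id)["validation"]
  permuted <- vapply(seq_len(n_permutations), function(i) {
    per <- dev
    per$omega <- sample(per$omega)
    cv_score(per, config, gs$hyper, fold_id)["validation"]
  }, numeric(1))
  p <- (1 + sum(permuted >= score)) / (1 + n_permutations)
  list(p_value = p, score = unname(score), permuted_scores = unname(permuted))
}

#' Sweep of regression experiments over feature combinations and betas
#'
#' Runs [run_experiment()] for every (feature combination, beta) cell
#' and returns the heatmap-ready table of test R^2 values, with the
#' per-combination minimum over betas as an attached summary.
#'
#' @param records data frame from [assemble_records()].
#' @param combos list of character vectors (feature combinations); the
#'   default is all eight single features.
#' @param betas numeric vector of betas present in the records.
#' @param config a [regression_config()].
#' @param seed integer seed; each cell gets a deterministic derived
#'   seed.
#' @return data frame (class `sweep_result`) with one row per cell and
#'   columns `combo`, `beta`, `n_rows`, `dev_size`, `r2_test`; the
#'   attribute `"summary"` holds the min-over-beta table.
#' @export
sweep_experiments <- function(records, combos = as.list(feature_names()),
                              betas = attr(records, "betas"),
                              config = regression_config(), seed = 1L) {
  stopifnot(length(combos) >= 1, length(betas) >= 1)
  rows <- list()
  cell <- 0L
  for (ci in seq_along(combos)) {
    for (beta in betas) {
      cell <- cell + 1L
      view <- project_and_dedup(records, combos[[ci]], beta)
      res <- tryCatch(
        run_experiment(view, config, seed = as.integer(seed) + cell),
        error = function(e) {
          warning("cell (", paste(combos[[ci]], collapse = "+"), ", beta = ",
                  beta, ") skipped: ", conditionMessage(e), call. = FALSE)
          NULL
        })
      rows[[cell]] <- data.frame(
        combo = paste(combos[[ci]], collapse = "+"), beta = beta,
        n_rows = nrow(view),
        dev_size = if (is.null(res)) NA_integer_ else res$dev_size,
        r2_test = if (is.null(res)) NA_real_ else res$r2_test)
    }
  }
  out <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(out, out$combo), function(d) {
    if (all(is.na(d$r2_test)))
      return(data.frame(combo = d$combo[1L], min_r2 = NA_real_,
                        worst_beta = NA_real_))
    data.frame(combo = d$combo[1L], min_r2 = min(d$r2_test, na.rm = TRUE),
               worst_beta = d$beta[which.min(d$r2_test)])
  }))
  summary <- summary[order(-summary$min_r2), ]
  rownames(summary) <- NULL
  attr(out, "summary") <- summary
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Minimum-over-beta summary of a sweep
#' @param x a `sweep_result` from [sweep_experiments()].
#' @return data frame with one row per combination.
#' @export
sweep_summary <- function(x) attr(x, "summary")
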
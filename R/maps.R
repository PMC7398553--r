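# Prediction maps: dense evaluation of a two-feature regressor over the
# unit square, with an achievability mask.
#
# A trained smooth (support-vector) regressor sees its two features as
# continuous, so evaluating it on a grid over [0,1]^2 draws a continuous
# map of the predicted outbreak size.  Real graphs only attain a sparse
# pattern of feature coordinates; grid cells containing no observed
# (feature1, feature2) point are flagged unattainable so the map can be
# read without over-interpreting regions where no graph exists.

#' Build a prediction map from a trained two-feature model
#'
#' Evaluates the model at the center of every cell of a
#' `resolution x resolution` grid over the unit square and marks each
#' cell attainable iff at least one observed data point of the view
#' falls inside it.
#'
#' @param model a model returned by [run_experiment()] (`$model`) or
#'   [fit_model] wrapper, trained on exactly two features with the
#'   `svm` regressor.
#' @param view the `experiment_view` the model was trained on (supplies
#'   the observed feature coordinates for the mask).
#' @param feature_pair character vector of the two feature names, in
#'   (x, y) order.
#' @param resolution grid cells per axis (default 100).
#' @return object of class `prediction_map`: a data frame with columns
#'   `x`, `y` (cell centers), `omega_hat`, `attainable`, plus
#'   attributes `features`, `resolution`, `beta`.
#' @export
build_map <- function(model, view, feature_pair, resolution = 100L) {
  stopifnot(inherits(model, "sirpredict_model"), length(feature_pair) == 2)
  if (!setequal(model$features, feature_pair))
    stop("model was trained on features (",
         paste(model$features, collapse = ", "),
         "), not on the requested pair")
  if (model$config$regressor != "svm")
    stop("prediction maps require the smooth (svm) regressor")
  r <- as.integer(resolution)
  stopifnot(r >= 2)
  centers <- (seq_len(r) - 0.5) / r
  grid <- expand.grid(x = centers, y = centers)
  newdata <- stats::setNames(grid, feature_pair)
  grid$omega_hat <- predict(model, newdata)
  cx <- pmin(pmax(ceiling(view[[feature_pair[1L]]] * r), 1L), r)
  cy <- pmin(pmax(ceiling(view[[feature_pair[2L]]] * r), 1L), r)
  occupied <- unique((cy - 1L) * r + cx)
  cell <- (match(grid$y, centers) - 1L) * r + match(grid$x, centers)
  grid$attainable <- cell %in% occupied
  structure(grid, features = feature_pair, resolution = r,
            beta = attr(view, "beta"),
            class = c("prediction_map", "data.frame"))
}

#' Series of prediction maps across betas or graph sizes
#'
#' For a fixed graph size, trains one support-vector model per beta on
#' the deduplicated (feature pair, omega) view and maps it
#' (`series = "beta"`).  For a size series (`series = "size"`),
#' `records` is a list of record tables (one per N), beta is fixed, and
#' the mapped quantity is the per-node outbreak fraction omega/N so
#' that sizes are comparable.
#'
#' @param records an [assemble_records()] table, or a list of them
#'   (named by N) for `series = "size"`.
#' @param feature_pair two feature names.
#' @param betas betas to map (beta series), or a single beta (size
#'   series).
#' @param series "beta" or "size".
#' @param config a [regression_config()]; must use the svm regressor.
#' @param resolution grid cells per axis.
#' @param seed integer seed.
#' @return named list of `prediction_map` objects.
#' @export
map_series <- function(records, feature_pair, betas = beta_grid(),
                       series = c("beta", "size"),
                       config = regression_config("svm"),
                       resolution = 100L, seed = 1L) {
  series <- match.arg(series)
  if (config$regressor != "svm")
    stop("prediction maps require the smooth (svm) regressor")
  if (series == "beta") {
    stopifnot(is.data.frame(records))
    maps <- lapply(betas, function(beta) {
      view <- project_and_dedup(records, feature_pair, beta)
      res <- run_experiment(view, config, seed = seed)
      build_map(res$model, view, feature_pair, resolution)
    })
    names(maps) <- beta_label(betas)
  } else {
    stopifnot(is.list(records), !is.data.frame(records), length(betas) == 1)
    maps <- lapply(records, function(rec) {
      n_nodes <- length(unique(rec$node))
      view <- project_and_dedup(rec, feature_pair, betas)
      view$omega <- view$omega / n_nodes # outbreak fraction, comparable across N
      res <- run_experiment(view, config, seed = seed)
      m <- build_map(res$model, view, feature_pair, resolution)
      attr(m, "target") <- "omega_fraction"
      m
    })
  }
  maps
}
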
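# Per-node records joining centrality features to exact outbreak sizes.
#
# One record per (graph, node): eight predictor values plus the exact
# outbreak size for every beta on the grid, in wide columns named
# omega_<beta>.  The learning protocol then projects a record set onto a
# feature combination and one beta, and removes exact duplicates (rows
# identical on selected features AND target) so that no test row can be
# identical to a training row.  Rows with equal features but different
# targets are NOT duplicates and are kept: they are irreducible
# prediction error, part of what the analysis measures.

omega_col <- function(beta) paste0("omega_", beta_label(beta))

#' Assemble per-node feature/target records
#'
#' Inner-joins a feature table ([featurize()]) with a long outbreak
#' table ([solve_graphs()]), spreading the betas into wide
#' `omega_<beta>` columns.  Both inputs must cover exactly the same
#' (graph_id, node) pairs.
#'
#' @param features data frame from [featurize()].
#' @param omega data frame from [solve_graphs()] with columns
#'   `graph_id`, `seed`, `beta`, `omega`.
#' @return data frame with feature columns and one `omega_<beta>`
#'   column per beta.
#' @export
assemble_records <- function(features, omega) {
  stopifnot(all(c("graph_id", "node", feature_names()) %in% names(features)),
            all(c("graph_id", "seed", "beta", "omega") %in% names(omega)))
  fkey <- paste(features$graph_id, features$node)
  okey <- unique(paste(omega$graph_id, omega$seed))
  miss_f <- setdiff(okey, fkey)
  miss_o <- setdiff(fkey, okey)
  if (length(miss_f) || length(miss_o))
    stop("features and omega tables cover different (graph, node) sets; ",
         "missing from features: ", paste(utils::head(miss_f, 5), collapse = ", "),
         "; missing from omega: ", paste(utils::head(miss_o, 5), collapse = ", "))
  betas <- sort(unique(omega$beta))
  wide <- stats::reshape(
    omega[order(omega$graph_id, omega$seed, omega$beta), ],
    idvar = c("graph_id", "seed"), timevar = "beta", direction = "wide")
  names(wide) <- sub("^omega\\.", "", names(wide))
  names(wide)[-(1:2)] <- vapply(betas, omega_col, character(1))
  out <- merge(features, wide, by.x = c("graph_id", "node"),
               by.y = c("graph_id", "seed"), sort = FALSE)
  out <- out[order(out$graph_id, out$node, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "betas") <- betas
  out
}

#' Project records onto a feature combination and deduplicate
#'
#' Selects the requested feature columns plus the outbreak-size column
#' for one beta, then drops exact duplicate rows (identical on all
#' selected features and the target; first occurrence wins).  Exact
#' duplicates arise primarily from automorphically equivalent nodes and
#' would otherwise leak training rows into the test set.
#'
#' @param records data frame from [assemble_records()].
#' @param feature_combo non-empty character vector of feature names.
#' @param beta a single beta present in the records.
#' @return an `experiment_view`: data frame with the feature columns and
#'   an `omega` target column, with attributes `beta`, `features`, `n`.
#' @export
project_and_dedup <- function(records, feature_combo, beta) {
  stopifnot(length(feature_combo) >= 1)
  unknown <- setdiff(feature_combo, feature_names())
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  oc <- omega_col(beta)
  if (!oc %in% names(records))
    stop("no outbreak-size column for beta = ", beta, " in records")
  view <- records[, c(feature_combo, oc)]
  names(view)[ncol(view)] <- "omega"
  # duplicates are identified on values rounded to 12 significant
  # digits: orbit-equivalent nodes yield equal values up to solver and
  # linear-algebra round-off, and must collapse to one row
  key <- do.call(paste, c(lapply(view, signif, digits = 12), sep = "\r"))
  view <- view[!duplicated(key), , drop = FALSE]
  rownames(view) <- NULL
  structure(view, beta = beta, features = feature_combo,
            n_nodes = attr(records, "n_nodes"),
            class = c("experiment_view", "data.frame"))
}
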
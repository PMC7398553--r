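# End-to-end pipeline: enumerate -> solve -> featurize -> dataset ->
# sweep, driven by a small plain-text configuration, with a manifest
# recording checksums so unchanged stages are skipped on re-run.

#' Parse a pipeline configuration
#'
#' Accepts either a named list or the path of a plain-text key=value
#' file (one pair per line, `#` comments allowed).  Recognized keys:
#' `n` (graph size), `betas` (comma-separated, default the nine-value
#' grid), `max_combo` (largest feature-combination size swept, default
#' 1), `regressor` ("forest"/"svm"), `dev_fraction`, `seed`, `out_dir`.
#'
#' @param config named list or file path.
#' @return object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    lines <- readLines(config, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- stats::setNames(
      lapply(kv, function(p) trimws(paste(p[-1L], collapse = "="))),
      trimws(vapply(kv, `[[`, character(1), 1L)))
  }
  stopifnot(is.list(config), !is.null(config$n), !is.null(config$out_dir))
  cfg <- list(
    n = as.integer(config$n),
    betas = if (is.null(config$betas)) beta_grid()
            else as.numeric(strsplit(as.character(config$betas), ",")[[1L]]),
    max_combo = if (is.null(config$max_combo)) 1L else as.integer(config$max_combo),
    regressor = if (is.null(config$regressor)) "forest" else as.character(config$regressor),
    dev_fraction = if (is.null(config$dev_fraction)) 0.75 else as.numeric(config$dev_fraction),
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    out_dir = as.character(config$out_dir))
  stopifnot(cfg$n >= 2, cfg$n <= 10, cfg$max_combo >= 1, cfg$max_combo <= 3)
  structure(cfg, class = "run_config")
}

stage_hash <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(utils::capture.output(utils::str(list(...))), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) enumerate the connected nonisomorphic ensemble and write
#' it as graph6; (2) exact outbreak sizes for every (graph, seed, beta)
#' as CSV; (3) centrality features as CSV; (4) joined per-node record
#' table as CSV; (5) regression sweep over all feature combinations up
#' to `max_combo` as CSV.  A `manifest.json` with per-stage input
#' hashes and output checksums makes re-runs idempotent: a stage whose
#' configuration and output are unchanged is skipped.
#'
#' @param config a [run_config()], a named list, or a config file path.
#' @return (invisibly) the manifest: named list of produced files with
#'   md5 checksums.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()

  paths <- list(graphs = file.path(cfg$out_dir, "graphs.g6"),
                omega = file.path(cfg$out_dir, "omega.csv"),
                features = file.path(cfg$out_dir, "features.csv"),
                dataset = file.path(cfg$out_dir, "dataset.csv"),
                sweep = file.path(cfg$out_dir, "sweep.csv"))

  fresh <- function(stage, hash) {
    rec <- manifest[[stage]]
    !is.null(rec) && identical(rec$hash, hash) && file.exists(paths[[stage]]) &&
      identical(unname(tools::md5sum(paths[[stage]])), rec$md5)
  }
  record <- function(stage, hash) {
    manifest[[stage]] <<- list(file = paths[[stage]], hash = hash,
                               md5 = unname(tools::md5sum(paths[[stage]])))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(stage, hash, compute) {
    if (fresh(stage, hash)) {
      message("stage ", stage, ": up to date, skipping")
      return(invisible(FALSE))
    }
    message("stage ", stage, ": running")
    compute()
    record(stage, hash)
    invisible(TRUE)
  }

  h_enum <- stage_hash("enumerate", cfg$n)
  run_stage("graphs", h_enum, function() {
    write_graph6(enumerate_connected_graphs(cfg$n), paths$graphs)
  })
  graphs <- enumerate_connected_graphs(cfg$n)

  h_solve <- stage_hash("solve", h_enum, cfg$betas)
  run_stage("omega", h_solve, function() {
    utils::write.csv(solve_graphs(graphs, sir_parameters(cfg$betas)),
                     paths$omega, row.names = FALSE)
  })

  h_feat <- stage_hash("featurize", h_enum)
  run_stage("features", h_feat, function() {
    utils::write.csv(featurize(graphs), paths$features, row.names = FALSE)
  })

  h_data <- stage_hash("dataset", h_solve, h_feat)
  run_stage("dataset", h_data, function() {
    features <- utils::read.csv(paths$features)
    omega <- utils::read.csv(paths$omega)
    utils::write.csv(assemble_records(features, omega), paths$dataset,
                     row.names = FALSE)
  })

  h_sweep <- stage_hash("sweep", h_data, cfg$max_combo, cfg$regressor,
                        cfg$dev_fraction, cfg$seed)
  run_stage("sweep", h_sweep, function() {
    records <- utils::read.csv(paths$dataset)
    attr(records, "betas") <- cfg$betas
    combos <- unlist(lapply(seq_len(cfg$max_combo), function(k) {
      utils::combn(feature_names(), k, simplify = FALSE)
    }), recursive = FALSE)
    rc <- regression_config(cfg$regressor, dev_fraction = cfg$dev_fraction)
    sw <- sweep_experiments(records, combos, cfg$betas, rc, seed = cfg$seed)
    utils::write.csv(sw, paths$sweep, row.names = FALSE)
  })

  invisible(jsonlite::read_json(manifest_path))
}
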
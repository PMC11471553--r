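#' Run configuration
#'
#' One configuration object for the end-to-end pipeline, with blocks per
#' stage. Unknown keys at any level are rejected so a typo in a YAML
#' file cannot silently fall back to a default.
#'
#' @param generator List of [generator_config()] arguments.
#' @param features List of [feature_config()] arguments.
#' @param split List of [split_spec()] arguments.
#' @param network List with `hidden` (integer vector).
#' @param pso List of [pso_config()] arguments.
#' @param evaluation List with `importance` (logical) and
#'   `importance_repeats`.
#' @param seed Global seed filled into any stage seed left unset.
#' @param out_dir Output directory for artifacts.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(generator = list(), features = list(),
                       split = list(), network = list(), pso = list(),
                       evaluation = list(), seed = 42,
                       out_dir = "annpso-run") {
  check_keys <- function(given, allowed, block) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown) > 0) {
      abort(paste0("Unknown key(s) in `", block, "`: ",
                   paste(unknown, collapse = ", ")), class = "annpso_config_error")
    }
  }
  check_keys(generator, names(formals(generator_config)), "generator")
  check_keys(features, names(formals(feature_config)), "features")
  check_keys(split, names(formals(split_spec)), "split")
  check_keys(network, c("hidden", "loss"), "network")
  check_keys(pso, c(names(formals(pso_config)), "restarts"), "pso")
  check_keys(evaluation, c("importance", "importance_repeats"), "evaluation")
  if (is.null(generator$seed)) generator$seed <- seed
  if (is.null(split$seed)) split$seed <- seed
  if (is.null(pso$seed)) pso$seed <- seed
  if (is.null(pso$r_mode)) pso$r_mode <- "dimension"
  if (is.null(pso$bounds)) pso$bounds <- c(-0.25, 0.25)
  if (is.null(pso$k_max)) pso$k_max <- 150
  evaluation <- utils::modifyList(list(importance = FALSE,
                                       importance_repeats = 5), evaluation)
  structure(list(generator = generator, features = features, split = split,
                 network = network, pso = pso, evaluation = evaluation,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any of the blocks `generator`, `features`,
#'   `split`, `network`, `pso`, `evaluation`, and scalars `seed`,
#'   `out_dir`.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "annpso_config_error")
  }
  raw <- yaml::read_yaml(path)
  allowed <- c("generator", "features", "split", "network", "pso",
               "evaluation", "seed", "out_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown top-level key(s): ", paste(unknown, collapse = ", ")),
          class = "annpso_config_error")
  }
  if (!is.null(raw$network$hidden)) raw$network$hidden <- as.integer(raw$network$hidden)
  do.call(run_config, raw)
}

write_csv_atomic <- function(data, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_csv(data, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

report_payload <- function(report, curves) {
  list(
    accuracy = report$accuracy,
    macro = report$macro,
    per_class = report$per_class,
    confusion = unclass(report$cm),
    macro_roc_auc = curves$macro_roc_auc,
    macro_pr_auc = curves$macro_pr_auc,
    auc = curves$auc
  )
}

#' Run the full pipeline
#'
#' Generate (or load) a cohort, train the hybrid classifier, evaluate on
#' the held-out test split, and write all artifacts to `out_dir`:
#' `dataset.csv`, `model.json`, `report.json`, `curves.csv`,
#' `history.csv` and optionally `importance.csv`. All files are written
#' atomically (temp + rename), so a failed run leaves no partial
#' outputs. Given equal seeds, a rerun produces byte-identical
#' artifacts.
#'
#' @param config A [run_config()].
#' @param data Optional pre-loaded cohort; when `NULL` (default) the
#'   synthetic generator runs with `config$generator`.
#' @param quiet Suppress progress messages?
#' @return The fitted `"ann_pso"` model, invisibly, with the artifact
#'   paths in attribute `"artifacts"`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(data)) {
    say("[generate] sampling %s records",
        config$generator$n_records %||% 2111)
    data <- generate_obesity_data(do.call(generator_config, config$generator))
  }
  paths <- list(dataset = file.path(config$out_dir, "dataset.csv"),
                model = file.path(config$out_dir, "model.json"),
                report = file.path(config$out_dir, "report.json"),
                curves = file.path(config$out_dir, "curves.csv"),
                history = file.path(config$out_dir, "history.csv"),
                importance = file.path(config$out_dir, "importance.csv"))
  write_csv_atomic(data, paths$dataset)

  say("[train] optimizing network weights by particle swarm")
  restarts <- config$pso$restarts %||% 2
  pso_args <- config$pso[setdiff(names(config$pso), "restarts")]
  fit <- train_ann_pso(
    data,
    hidden = config$network$hidden %||% c(128, 64, 32),
    pso = do.call(pso_config, pso_args),
    split = do.call(split_spec, config$split),
    features = do.call(feature_config, config$features),
    loss = config$network$loss %||% "mse",
    restarts = restarts
  )
  save_model(list(
    spec = fit$spec, weights = fit$weights, seed = config$seed,
    features = fit$features,
    feature_config = unclass(fit$feature_config),
    scaler = unclass(fit$scaler),
    tue_range = fit$tue_scaler$range
  ), paths$model)
  write_csv_atomic(fit$history, paths$history)

  say("[evaluate] test accuracy %.4f", fit$test$accuracy)
  curves <- roc_pr_curves(fit$test_y, fit$test_probs,
                          class_names = bmi_class_table("seven")$class)
  write_csv_atomic(curves$points, paths$curves)
  write_json_atomic(report_payload(fit$test, curves), paths$report,
                    dataframe = "columns")

  if (isTRUE(config$evaluation$importance)) {
    say("[evaluate] permutation importance")
    imp <- permutation_importance(
      function(M) predict_class(forward_pass(fit$spec, fit$weights, M)),
      X = fit$test_X, y = fit$test_y, seed = config$seed,
      n_repeats = config$evaluation$importance_repeats)
    write_csv_atomic(imp, paths$importance)
  }
  attr(fit, "artifacts") <- paths
  invisible(fit)
}

#' Restore a classifier from a saved model file
#'
#' Rebuilds a predict-ready classifier (network, weights, feature
#' engineering and scalers) from the self-contained `model.json` written
#' by [run_pipeline()].
#'
#' @param path Path to a model JSON file.
#' @return An `"ann_pso"` object usable with [predict.ann_pso()].
#' @export
restore_classifier <- function(path) {
  m <- load_model(path)
  stopifnot(!is.null(m$scaler), !is.null(m$feature_config))
  stat_names <- if (identical(m$scaler$mode, "zscore")) c("mean", "sd") else c("min", "max")
  scaler <- structure(list(
    mode = m$scaler$mode,
    columns = as.character(m$scaler$columns),
    stats = lapply(m$scaler$stats, function(s)
      setNames(as.numeric(unlist(s)), stat_names))
  ), class = "feature_scaler")
  structure(list(
    spec = m$spec, weights = m$weights,
    features = as.character(m$features),
    feature_config = do.call(feature_config, m$feature_config),
    scaler = scaler,
    tue_scaler = structure(list(range = as.numeric(m$tue_range)),
                           class = "tue_scaler")
  ), class = "ann_pso")
}

#' Demonstration run on the synthetic benchmark
#'
#' The packaged end-to-end benchmark: a synthetic cohort of `n` records
#' (default 3000, seed 42), height dropped, hybrid training with the
#' default swarm settings, and a test-set report.
#'
#' @param n Cohort size, default 3000.
#' @param seed Seed, default 42.
#' @param out_dir Output directory.
#' @param ... Overrides forwarded to [run_config()].
#' @return The fitted model, invisibly (see [run_pipeline()]).
#' @export
demo_pipeline <- function(n = 3000, seed = 42,
                          out_dir = file.path(tempdir(), "annpso-demo"),
                          ...) {
  cfg <- run_config(generator = list(n_records = n), seed = seed,
                    out_dir = out_dir, ...)
  run_pipeline(cfg)
}
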
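#' Assemble an end-to-end run configuration
#'
#' A run configuration ties the whole pipeline together: where the data come
#' from (a CSV path or a synthetic scenario), how they are preprocessed and
#' split, which base-model families are tuned, the weight-optimizer
#' settings, and where artifacts are written. Configurations can also be
#' read from a YAML/JSON file with [read_run_config()].
#'
#' @param data Path to a CSV with a header row, or `NULL` to generate from
#'   `scenario`.
#' @param scenario A [scenario_spec()] (or list of its arguments) used when
#'   `data` is `NULL`.
#' @param target_column,positive_label,positive_classes Target handling for
#'   CSV input; see [read_feature_table()].
#' @param zero_columns Columns whose zeros are invalid and imputed.
#' @param impute_strategy `"median"` or `"min"` for invalid zeros.
#' @param fractions Train/val/test fractions, default `c(0.6, 0.2, 0.2)`.
#' @param seed Master seed for the split and all tuning.
#' @param families Base-model families to include, default all five.
#' @param grids Optional named list of per-family hyperparameter grids.
#' @param k_folds Cross-validation folds for tuning, default 5.
#' @param gbwoem A [gbwoem_config()] or list of its arguments.
#' @param selection `"validation"` (default) or `"test"` subset selection.
#' @param min_size Smallest ensemble size searched, default 2.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(data = NULL, scenario = scenario_spec(),
                       target_column = NULL, positive_label = NULL,
                       positive_classes = NULL, zero_columns = NULL,
                       impute_strategy = "median",
                       fractions = c(0.6, 0.2, 0.2), seed = 1L,
                       families = BASE_FAMILIES, grids = NULL, k_folds = 5L,
                       gbwoem = gbwoem_config(), selection = "validation",
                       min_size = 2L, out_dir = tempfile("gbwoem_run_")) {
  if (is.list(scenario) && !inherits(scenario, "scenario_spec")) {
    scenario <- do.call(scenario_spec, scenario)
  }
  if (is.list(gbwoem) && !inherits(gbwoem, "gbwoem_config")) {
    gbwoem <- do.call(gbwoem_config, gbwoem)
  }
  structure(
    list(data = data, scenario = scenario, target_column = target_column,
         positive_label = positive_label, positive_classes = positive_classes,
         zero_columns = zero_columns, impute_strategy = impute_strategy,
         fractions = fractions, seed = as.integer(seed), families = families,
         grids = grids, k_folds = as.integer(k_folds), gbwoem = gbwoem,
         selection = selection, min_size = as.integer(min_size),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file whose keys are [run_config()] arguments (the
#'   `scenario` and `gbwoem` entries may be nested argument lists).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  do.call(run_config, yaml::read_yaml(path))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Generate a synthetic table and write it with its manifest
#'
#' Draws the configured scenario (applying its corruption rates), writes the
#' table as CSV in the same dialect the loader reads, and records the full
#' scenario plus seed in a JSON manifest so the file is reproducible
#' byte-for-byte.
#'
#' @param config A [run_config()] whose `scenario` is used.
#' @return Invisibly, a list with `csv` and `manifest` paths.
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$scenario
  tab <- generate_table(spec)
  if (spec$invalid_zero_rate > 0 || spec$missing_rate > 0) {
    tab <- corrupt_table(tab, spec, zero_columns = config$zero_columns)
  }
  csv <- file.path(config$out_dir, "synthetic.csv")
  readr::write_csv(tab, csv, progress = FALSE)
  manifest <- write_json_artifact(
    list(scenario = unclass(spec), rows = nrow(tab),
         columns = names(tab)),
    file.path(config$out_dir, "generate_manifest.json")
  )
  invisible(list(csv = csv, manifest = manifest))
}

load_or_generate <- function(config) {
  if (!is.null(config$data)) {
    read_feature_table(config$data, config$target_column,
                       positive_label = config$positive_label,
                       positive_classes = config$positive_classes)
  } else {
    paths <- run_generate(config)
    read_feature_table(paths$csv, ".outcome")
  }
}

#' Run the full ensemble pipeline and write its artifacts
#'
#' End to end: load (or generate) the table, impute invalid zeros, split
#' stratified into train/validation/test, encode/impute/scale with
#' training-fitted statistics, tune every base-model family by grid-search
#' CV, search all model subsets with gradient-optimized weights, and score
#' the winner. Artifacts written to `out_dir`:
#' `results.csv` (one row per subset), `best_ensemble.json`,
#' `best_trace.csv` (the winner's per-iteration losses),
#' `metrics.json` and `roc_val.csv`/`roc_test.csv` for the winner,
#' and `manifest.json` (seeds, fractions, scenario, chosen
#' hyperparameters) from which the run is reproducible.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `search` object, the fitted `models`,
#'   the `split`, and the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  tab <- load_or_generate(config)
  if (!is.null(config$zero_columns)) {
    tab <- impute_invalid_zeros(tab, config$zero_columns,
                                strategy = config$impute_strategy)
  }
  split <- stratified_split(tab, config$fractions, config$seed)
  split <- preprocess_split(split)

  models <- lapply(config$families, function(fam) {
    grid <- config$grids[[fam]] %||% default_grid(fam)
    tune_base_model(
      base_model_spec(fam, grid = grid, k_folds = config$k_folds,
                      seed = config$seed),
      split$train
    )
  })

  search <- search_combinations(models, split, config$gbwoem,
                                selection = config$selection,
                                min_size = config$min_size)
  best <- best_ensemble(search)
  best_fit <- search$fits[[search$best_index]]
  sub <- search$subsets[[search$best_index]]
  P_val <- predict_matrix(models, split$val)[sub, , drop = FALSE]
  P_test <- predict_matrix(models, split$test)[sub, , drop = FALSE]
  rep_val <- metrics_report(split$val$.outcome,
                            ensemble_predict(P_val, best_fit$weights))
  rep_test <- metrics_report(split$test$.outcome,
                             ensemble_predict(P_test, best_fit$weights))

  paths <- list(
    results = file.path(config$out_dir, "results.csv"),
    best = file.path(config$out_dir, "best_ensemble.json"),
    trace = file.path(config$out_dir, "best_trace.csv"),
    metrics = file.path(config$out_dir, "metrics.json"),
    roc_val = file.path(config$out_dir, "roc_val.csv"),
    roc_test = file.path(config$out_dir, "roc_test.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  readr::write_csv(tidy(search), paths$results, progress = FALSE)
  write_json_artifact(
    list(subset = sub, weights = as.list(best_fit$weights),
         selection = search$selection,
         best_loss = best_fit$best_loss,
         best_iteration = best_fit$best_iteration,
         iterations_run = best_fit$iterations_run,
         stop_reason = best_fit$stop_reason),
    paths$best
  )
  readr::write_csv(best_fit$trace, paths$trace, progress = FALSE)
  write_json_artifact(
    list(validation = as.list(rep_val$metrics),
         test = as.list(rep_test$metrics)),
    paths$metrics
  )
  readr::write_csv(rep_val$roc_points, paths$roc_val, progress = FALSE)
  readr::write_csv(rep_test$roc_points, paths$roc_test, progress = FALSE)
  write_json_artifact(
    list(
      seed = config$seed, fractions = config$fractions,
      families = config$families, k_folds = config$k_folds,
      selection = config$selection,
      scenario = if (is.null(config$data)) unclass(config$scenario) else NULL,
      data = config$data,
      gbwoem = unclass(config$gbwoem),
      chosen_hyperparameters = setNames(
        lapply(models, function(m) m$chosen_hyperparameters),
        vapply(models, function(m) m$family, character(1))
      ),
      split_indices = split$indices
    ),
    paths$manifest
  )
  invisible(list(search = search, models = models, split = split,
                 paths = paths, best = best))
}
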
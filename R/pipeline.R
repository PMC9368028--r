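#' Run the full training pipeline described by a run configuration
#'
#' Loads or generates the panel, imputes missing values, builds supervised
#' windows, splits chronologically, fits the scaler on the training portion,
#' trains the configured structure and evaluates it on the test portion.
#'
#' @param cfg a `run_config` from [load_config()] / [default_run_config()].
#' @param metrics metrics to report (see [evaluate()]).
#' @return A list with `panel`, `splits`, `scaler`, `fit` (a `wq_fit`) and
#'   `report` (a `metrics_report`).
#' @export
run_training_pipeline <- function(cfg, metrics = c("rmse", "mae", "mape")) {
  panel <- if (identical(cfg$data$source, "csv")) {
    impute_missing(read_panel_csv(cfg$data$path))
  } else {
    syn <- do.call(synthetic_config, cfg$data$synthetic)
    generate_panel(syn)
  }
  windows <- make_windows(panel, cfg$windows$lookback, cfg$windows$horizon)
  splits <- chronological_split(windows,
                                split_spec(cfg$split$train_fraction,
                                           cfg$split$val_fraction,
                                           cfg$split$test_fraction))
  scaler <- fit_scaler(splits$train)
  scaled <- lapply(splits, apply_scaler, scaler = scaler)
  scfg <- structure_config(structure = cfg$model$structure,
                           tower_type = cfg$model$tower_type,
                           tasks = cfg$model$tasks,
                           hidden_width = cfg$model$hidden_width,
                           gh_literal_fusion = isTRUE(cfg$model$gh_literal_fusion))
  model <- build_model(scfg, cfg$windows$lookback, dim(panel$values)[1L],
                       seed = cfg$seed)
  model <- init_output_bias(model, scaled$train)
  tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                       epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       seed = cfg$seed,
                       checkpoint = cfg$train$checkpoint)
  fit <- train_model(model, scaled$train, scaled$val, tcfg)
  report <- evaluate(fit$model, scaled$test, scaler, metrics = metrics)
  list(panel = panel, splits = scaled, scaler = scaler, fit = fit,
       report = report)
}
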
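#' Default run configuration
#'
#' The training protocol defaults: lookback 10 weeks, horizon 1,
#' 60/20/20 chronological split, learning rate 0.001, 100 epochs, batch
#' size 5.  Data defaults to the synthetic generator so a run needs no
#' external files.
#'
#' @return A nested list (class `run_config`) with sections `data`, `model`,
#'   `windows`, `split`, `train`, plus `seed` and `out_dir`.
#' @export
default_run_config <- function() {
  structure(list(
    data = list(source = "synthetic", path = NULL,
                synthetic = list(n_stations = 8L, n_weeks = 200L, seed = 1L)),
    model = list(structure = "gh", tower_type = "mlp",
                 tasks = WQ_INDICATORS, hidden_width = 64L,
                 gh_literal_fusion = FALSE),
    windows = list(lookback = 10L, horizon = 1L),
    split = list(train_fraction = 0.6, val_fraction = 0.2, test_fraction = 0.2),
    train = list(learning_rate = 0.001, epochs = 100L, batch_size = 5L,
                 checkpoint = "best_val"),
    seed = 1L,
    out_dir = "."
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults)) {
      wq_stop(sprintf("unknown configuration key: %s", here),
              "aquamtl_config_error")
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration from YAML or JSON
#'
#' Values in the file override the [default_run_config()] defaults; keys not
#' present in the defaults are rejected with the offending key named.  The
#' merged configuration is validated before being returned.
#'
#' @param path a `.yaml`/`.yml` or `.json` file, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      wq_stop(sprintf("config file not found: %s", path), "aquamtl_io_error")
    }
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user) > 0) cfg <- merge_config(unclass(cfg), user)
    class(cfg) <- "run_config"
  }
  viol <- validate_config(cfg)
  if (length(viol) > 0) {
    wq_stop(paste0("invalid configuration:\n  ", paste(viol, collapse = "\n  ")),
            "aquamtl_config_error", data = list(violations = viol))
  }
  cfg
}

#' List the violations in a run configuration
#'
#' @param cfg a `run_config` list.
#' @return Character vector of violation messages with path-like key names
#'   (empty when the configuration is valid).
#' @export
validate_config <- function(cfg) {
  v <- character()
  add <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  add(cfg$train$learning_rate > 0, "train.learning_rate must be > 0")
  add(cfg$train$epochs >= 1, "train.epochs must be >= 1")
  add(cfg$train$batch_size >= 1, "train.batch_size must be >= 1")
  fr <- c(cfg$split$train_fraction, cfg$split$val_fraction, cfg$split$test_fraction)
  add(all(fr >= 0) && abs(sum(fr) - 1) <= 1e-9,
      "split fractions must be non-negative and sum to 1")
  add(cfg$windows$lookback >= 1, "windows.lookback must be >= 1")
  add(cfg$windows$horizon >= 1, "windows.horizon must be >= 1")
  add(cfg$model$structure %in% c("hard", "soft", "gate", "gh", "single_task",
                                 "linear_baseline"),
      "model.structure must be one of hard/soft/gate/gh/single_task/linear_baseline")
  add(cfg$model$tower_type %in% c("mlp", "lstm", "gru", "cnn", "attention"),
      "model.tower_type must be one of mlp/lstm/gru/cnn/attention")
  add(length(cfg$model$tasks) >= 1, "model.tasks must be non-empty")
  add(cfg$model$hidden_width >= 1, "model.hidden_width must be >= 1")
  add(cfg$data$source %in% c("synthetic", "csv"),
      "data.source must be 'synthetic' or 'csv'")
  if (identical(cfg$data$source, "csv")) {
    add(is.character(cfg$data$path) && nzchar(cfg$data$path),
        "data.path must be set when data.source is 'csv'")
  }
  v
}

#' Hash of the canonical JSON serialisation of an object
#' @param x any JSON-serialisable object (typically a `run_config`).
#' @return MD5 hex string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  if (is.object(x)) x <- unclass(x)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the config and its hash,
#' the seed, package version, timestamps, input checksums and the list of
#' files the run produced.
#'
#' @param path manifest JSON path.
#' @param config the `run_config` used.
#' @param seed the run seed.
#' @param inputs character vector of input file paths (checksummed).
#' @param outputs character vector of files the run wrote.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    package = "aquamtl",
    version = as.character(utils::packageVersion("aquamtl")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = config_hash(config),
    config = if (is.object(config)) unclass(config) else config,
    input_checksums = if (length(inputs) > 0) {
      as.list(setNames(unname(tools::md5sum(inputs)), inputs))
    } else list(),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
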
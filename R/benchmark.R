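# Benchmark and ablation harnesses: train several configurations on
# identical splits and seeds and lay the metrics out as comparison grids.

bench_run_one <- function(panel, scfg, lookback, horizon, split, tcfg, metrics) {
  windows <- make_windows(panel, lookback, horizon)
  splits <- chronological_split(windows, split)
  scaler <- fit_scaler(splits$train)
  scaled <- lapply(splits, apply_scaler, scaler = scaler)
  model <- build_model(scfg, lookback, dim(panel$values)[1L], seed = tcfg$seed)
  model <- init_output_bias(model, scaled$train)
  fit <- train_model(model, scaled$train, scaled$val, tcfg)
  evaluate(fit$model, scaled$test, scaler, metrics = metrics)
}

bench_label <- function(scfg) {
  base <- c(hard = "Mt-Hard", soft = "Mt-Soft", gate = "Mt-Gate", gh = "Mt-GH",
            single_task = "Single-MLP", linear_baseline = "Linear")[scfg$structure]
  unname(base)
}

bench_collect <- function(panel, configs, labels, seeds, lookback, horizon,
                          split, epochs, batch_size, learning_rate, metrics) {
  tasks_all <- unique(unlist(lapply(configs, `[[`, "tasks")))
  rows <- list()
  runs <- list()
  for (ci in seq_along(configs)) {
    scfg <- configs[[ci]]
    acc <- list()
    for (seed in seeds) {
      tcfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                           batch_size = batch_size, seed = seed)
      res <- suppressWarnings(tryCatch(
        bench_run_one(panel, scfg, lookback, horizon, split, tcfg, metrics),
        error = function(e) e
      ))
      runs[[length(runs) + 1L]] <- data.frame(
        model = labels[ci], seed = seed,
        config_hash = config_hash(unclass(scfg)),
        status = if (inherits(res, "error")) conditionMessage(res) else "ok",
        stringsAsFactors = FALSE
      )
      if (!inherits(res, "error")) acc[[length(acc) + 1L]] <- res
    }
    cell <- setNames(rep(NA_real_, length(tasks_all) * length(metrics)),
                     as.vector(outer(tasks_all, metrics, paste, sep = "_")))
    if (length(acc) > 0) {
      for (t in scfg$tasks) {
        for (m in metrics) {
          vals <- vapply(acc, function(r) {
            r$per_indicator[[m]][r$per_indicator$indicator == t]
          }, numeric(1))
          cell[paste(t, m, sep = "_")] <- mean(vals)
        }
      }
    }
    rows[[ci]] <- c(list(model = labels[ci]), as.list(cell))
  }
  list(per_indicator = do.call(rbind, lapply(rows, as.data.frame)),
       runs = do.call(rbind, runs), tasks = tasks_all)
}

aggregate_grid <- function(per_indicator, tasks, metrics,
                           baseline_models, candidate_model) {
  agg <- data.frame(model = per_indicator$model, stringsAsFactors = FALSE)
  for (m in metrics) {
    cols <- paste(tasks, m, sep = "_")
    agg[[m]] <- apply(per_indicator[, cols, drop = FALSE], 1L, function(x) {
      if (anyNA(x)) NA_real_ else aggregate_multi(x)
    })
  }
  improv <- c(list(model = "Improv."),
              setNames(rep(list(NA_real_), length(metrics)), metrics))
  base_rows <- agg$model %in% baseline_models
  cand_row <- agg$model == candidate_model
  if (any(base_rows) && any(cand_row)) {
    for (m in metrics) {
      ref <- suppressWarnings(min(agg[[m]][base_rows], na.rm = TRUE))
      cand <- agg[[m]][cand_row][1L]
      if (is.finite(ref) && ref > 0 && is.finite(cand)) {
        improv[[m]] <- relative_improvement(ref, cand)
      }
    }
  }
  rbind(agg, as.data.frame(improv))
}

#' Benchmark several sharing structures on one panel
#'
#' Trains every requested structure on identical chronological splits and
#' seeds, then lays out a per-indicator metric grid and a multi-indicator
#' aggregate grid with an improvement row (the candidate structure against
#' the best baseline structure).  A failed run leaves its cells missing and
#' the harness continues; every run's seed and config hash is recorded.
#'
#' @param panel a complete [indicator_panel()].
#' @param structures structures to compare (see [structure_config()]).
#' @param seeds one or more seeds; cell values average over seeds.
#' @param lookback,horizon window parameters.
#' @param split a [split_spec()].
#' @param hidden_width,epochs,batch_size,learning_rate shared model/training
#'   settings.
#' @param tasks indicators predicted jointly.
#' @param metrics metrics to tabulate.
#' @param candidate model label measured by the improvement row
#'   (default `"Mt-GH"`); baselines are the single-task and linear rows.
#' @return A list with `per_indicator` (grid of indicator-metric cells),
#'   `aggregate` (aggregate grid plus `Improv.` row) and `runs` (provenance).
#' @export
run_benchmark <- function(panel,
                          structures = c("hard", "soft", "gate", "gh",
                                         "single_task", "linear_baseline"),
                          seeds = 1L, lookback = 10L, horizon = 1L,
                          split = split_spec(), hidden_width = 64L,
                          epochs = 100L, batch_size = 5L, learning_rate = 0.001,
                          tasks = WQ_INDICATORS,
                          metrics = c("rmse", "mae", "mape"),
                          candidate = "Mt-GH") {
  configs <- lapply(structures, function(s) {
    structure_config(structure = s, tasks = tasks, hidden_width = hidden_width)
  })
  labels <- vapply(configs, bench_label, character(1))
  got <- bench_collect(panel, configs, labels, seeds, lookback, horizon, split,
                       epochs, batch_size, learning_rate, metrics)
  agg <- aggregate_grid(got$per_indicator, got$tasks, metrics,
                        baseline_models = c("Single-MLP", "Linear"),
                        candidate_model = candidate)
  list(per_indicator = got$per_indicator, aggregate = agg, runs = got$runs)
}

#' Task-subset (4-task vs 3-task) ablation grid
#'
#' Trains the same structure on the full task set and on each requested
#' subset; excluded indicators' cells stay blank (`NA`) in the grid.
#'
#' @inheritParams run_benchmark
#' @param structure the sharing structure to ablate (default `"gh"`).
#' @param task_subsets list of task subsets; defaults to the full set plus
#'   every leave-one-out triple.
#' @return A list with `grid` (per-indicator metric cells, one row per
#'   subset) and `runs` (provenance).
#' @export
run_task_ablation <- function(panel, structure = "gh",
                              task_subsets = NULL, seeds = 1L,
                              lookback = 10L, horizon = 1L,
                              split = split_spec(), hidden_width = 64L,
                              epochs = 100L, batch_size = 5L,
                              learning_rate = 0.001,
                              tasks = WQ_INDICATORS,
                              metrics = c("rmse", "mae", "mape")) {
  if (is.null(task_subsets)) {
    task_subsets <- c(list(tasks),
                      lapply(seq_along(tasks), function(i) tasks[-i]))
  }
  configs <- lapply(task_subsets, function(ts) {
    structure_config(structure = structure, tasks = ts,
                     hidden_width = hidden_width)
  })
  labels <- vapply(task_subsets, function(ts) {
    if (length(ts) == length(tasks)) sprintf("%d-task", length(ts))
    else sprintf("%d-task (-%s)", length(ts), setdiff(tasks, ts)[1L])
  }, character(1))
  got <- bench_collect(panel, configs, labels, seeds, lookback, horizon, split,
                       epochs, batch_size, learning_rate, metrics)
  list(grid = got$per_indicator, runs = got$runs)
}

#' Tower-type ablation grid
#'
#' Trains one sharing structure with each requested tower type.
#'
#' @inheritParams run_task_ablation
#' @param tower_types tower layers to compare.
#' @return A list with `grid` (one row per tower type) and `runs`.
#' @export
run_tower_ablation <- function(panel, structure = "gh",
                               tower_types = c("lstm", "gru", "cnn",
                                               "attention", "mlp"),
                               seeds = 1L, lookback = 10L, horizon = 1L,
                               split = split_spec(), hidden_width = 64L,
                               epochs = 100L, batch_size = 5L,
                               learning_rate = 0.001,
                               tasks = WQ_INDICATORS,
                               metrics = c("rmse", "mae", "mape")) {
  configs <- lapply(tower_types, function(tt) {
    structure_config(structure = structure, tower_type = tt, tasks = tasks,
                     hidden_width = hidden_width)
  })
  got <- bench_collect(panel, configs, toupper(tower_types), seeds, lookback,
                       horizon, split, epochs, batch_size, learning_rate,
                       metrics)
  list(grid = got$per_indicator, runs = got$runs)
}
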
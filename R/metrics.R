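check_metric_input <- function(y, yhat) {
  wq_assert(length(y) >= 1L, "empty input to metric", "aquamtl_empty_error")
  wq_assert(length(y) == length(yhat), "y and yhat lengths differ",
            "aquamtl_dim_error")
}

#' Root mean square error
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return `mean(abs(y - yhat))`.
#' @export
mae <- function(y, yhat) {
  check_metric_input(y, yhat)
  mean(abs(y - yhat))
}

#' Mean absolute percentage error (as a fraction)
#'
#' Relative error is undefined at zero targets, so any `|y|` below `epsilon`
#' raises a structured error naming the offending indices.  Multiply by 100
#' for a percentage.
#'
#' @inheritParams rmse
#' @param epsilon guard below which a target counts as zero (default 1e-8).
#' @return `mean(abs((y - yhat) / y))`, a fraction.
#' @export
mape <- function(y, yhat, epsilon = 1e-8) {
  check_metric_input(y, yhat)
  bad <- which(abs(y) < epsilon)
  if (length(bad) > 0L) {
    wq_stop(sprintf("MAPE undefined: %d target(s) within %g of zero (indices %s%s)",
                    length(bad), epsilon,
                    paste(head(bad, 5L), collapse = ", "),
                    if (length(bad) > 5L) ", ..." else ""),
            "aquamtl_mape_error", data = list(indices = bad))
  }
  mean(abs((y - yhat) / y))
}

#' Aggregate a per-indicator metric across indicators
#'
#' The multi-indicator table values equal the *sum* of the per-indicator
#' values, so sum is the default; the arithmetic mean is available as an
#' alternative convention.
#'
#' @param values numeric vector, one metric value per indicator.
#' @param method `"sum"` (default) or `"mean"`.
#' @return A single aggregate value.
#' @export
aggregate_multi <- function(values, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (method == "sum") sum(values) else mean(values)
}

round_half_away <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Relative improvement of a candidate over a reference, in percent
#'
#' `100 * (reference - candidate) / reference`, rounded half-away-from-zero
#' to one decimal — the convention of the comparison tables, where the
#' reference is the best competing (second-best overall) model.
#'
#' @param reference the baseline metric value (> 0).
#' @param candidate the improved model's metric value.
#' @return Improvement percentage, one decimal.
#' @export
relative_improvement <- function(reference, candidate) {
  if (!isTRUE(reference > 0)) {
    wq_stop("improvement reference must be > 0", "aquamtl_metric_error")
  }
  round_half_away(100 * (reference - candidate) / reference, 1L)
}

#' Evaluate a trained model on test windows, on the original scale
#'
#' Predicts the scaled test windows, inverts the scaler, flattens the
#' (sample, station) values per indicator, computes the requested metrics
#' per indicator and then their cross-indicator aggregate.
#'
#' @param model a trained `wq_model` (e.g. `fit$model`).
#' @param test_windows *scaled* test `supervised_windows`.
#' @param scaler the [fit_scaler()] result used to scale the data.
#' @param metrics which of `"rmse"`, `"mae"`, `"mape"` to compute.
#' @param aggregate aggregation convention passed to [aggregate_multi()].
#' @return An object of class `metrics_report`: `per_indicator` (data frame,
#'   one row per task), `aggregate` (named vector), and `n` (evaluated
#'   values per indicator = samples x stations).
#' @export
evaluate <- function(model, test_windows, scaler,
                     metrics = c("rmse", "mae", "mape"),
                     aggregate = "sum") {
  metrics <- match.arg(metrics, several.ok = TRUE)
  tasks <- model$config$tasks
  preds <- predict(model, test_windows, scaler = scaler)
  truth <- windows_to_targets(test_windows, tasks)
  truth <- lapply(setNames(tasks, tasks), function(t) {
    invert_indicator(truth[[t]], scaler, t)
  })
  fns <- list(rmse = rmse, mae = mae, mape = mape)
  per <- data.frame(indicator = tasks, stringsAsFactors = FALSE)
  for (m in metrics) {
    per[[m]] <- vapply(tasks, function(t) {
      fns[[m]](as.vector(truth[[t]]), as.vector(preds[[t]]))
    }, numeric(1))
  }
  agg <- vapply(metrics, function(m) aggregate_multi(per[[m]], aggregate),
                numeric(1))
  structure(list(per_indicator = per, aggregate = agg,
                 n = length(truth[[1L]])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d values per indicator\n", x$n))
  print(x$per_indicator, row.names = FALSE, digits = 4)
  cat("aggregate:", paste(sprintf("%s=%.4f", names(x$aggregate), x$aggregate),
                          collapse = "  "), "\n")
  invisible(x)
}

#' Export a metrics report as a plain list (for JSON serialisation)
#' @param report a [evaluate()] result.
#' @return A nested list mirroring the report.
#' @export
report_as_list <- function(report) {
  list(per_indicator = report$per_indicator,
       aggregate = as.list(report$aggregate),
       n = report$n)
}
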
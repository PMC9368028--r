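#' Build sliding supervised windows from a panel
#'
#' Every maximal contiguous lookback window is paired with the measurement
#' `horizon` steps after its end, yielding the supervised pairs
#' (x_1..x_lookback) -> y for one-step-ahead (or multi-step) forecasting.
#'
#' @param panel a complete [indicator_panel()] (no missing values).
#' @param lookback number of past weeks per input window (>= 1).
#' @param horizon forecast lead in weeks (>= 1, default 1).
#' @return An object of class `supervised_windows` with elements
#'   `X` (sample, lookback, station, indicator), `Y` (sample, station,
#'   indicator), `lookback`, `horizon`, `target_times` and the panel metadata.
#'   The sample count is `T - lookback - horizon + 1` (0 when negative).
#' @export
make_windows <- function(panel, lookback, horizon = 1L) {
  wq_assert(inherits(panel, "indicator_panel"), "`panel` must be an indicator_panel")
  wq_assert(!anyNA(panel$values), "panel contains missing values; impute first",
            "aquamtl_missing_error")
  lookback <- as.integer(lookback); horizon <- as.integer(horizon)
  wq_assert(lookback >= 1L && horizon >= 1L, "lookback and horizon must be >= 1")
  nt <- n_times(panel)
  if (nt == 0L) wq_stop("panel has no time points", "aquamtl_empty_error")
  ns <- dim(panel$values)[1L]; ni <- dim(panel$values)[3L]
  n <- max(0L, nt - lookback - horizon + 1L)
  X <- array(0, dim = c(n, lookback, ns, ni))
  Y <- array(0, dim = c(n, ns, ni))
  tt <- rep(as.Date(NA), n)
  for (k in seq_len(n)) {
    idx <- k:(k + lookback - 1L)
    X[k, , , ] <- aperm(panel$values[, idx, , drop = FALSE], c(2L, 1L, 3L))
    Y[k, , ] <- panel$values[, k + lookback + horizon - 1L, ]
    tt[k] <- panel$timestamps[k + lookback + horizon - 1L]
  }
  structure(
    list(X = X, Y = Y, lookback = lookback, horizon = horizon,
         target_times = tt, station_ids = panel$station_ids,
         indicator_names = panel$indicator_names, units = panel$units),
    class = "supervised_windows"
  )
}

#' @export
print.supervised_windows <- function(x, ...) {
  cat(sprintf("<supervised_windows> %d samples, lookback %d, horizon %d, %d stations, %d indicators\n",
              n_samples(x), x$lookback, x$horizon,
              dim(x$X)[3L], dim(x$X)[4L]))
  invisible(x)
}

#' Number of supervised samples
#' @param windows a [make_windows()] result.
#' @return integer sample count.
#' @export
n_samples <- function(windows) dim(windows$X)[1L]

subset_windows <- function(windows, idx) {
  out <- windows
  out$X <- windows$X[idx, , , , drop = FALSE]
  out$Y <- windows$Y[idx, , , drop = FALSE]
  out$target_times <- windows$target_times[idx]
  out
}

#' Chronological train/validation/test split specification
#'
#' @param train_fraction,val_fraction,test_fraction non-negative fractions
#'   summing to 1 (default 0.6/0.2/0.2).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.6, val_fraction = 0.2,
                       test_fraction = 0.2) {
  fr <- c(train_fraction, val_fraction, test_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    wq_stop("split fractions must be non-negative and sum to 1",
            "aquamtl_split_error")
  }
  structure(list(train_fraction = train_fraction, val_fraction = val_fraction,
                 test_fraction = test_fraction), class = "split_spec")
}

#' Split supervised windows chronologically
#'
#' The earliest `floor(train_fraction * n)` samples form the training set, the
#' next `floor(val_fraction * n)` the validation set, and all remaining
#' (later) samples the test set, so no future information leaks backwards.
#'
#' @param windows a [make_windows()] result, samples ordered by target time.
#' @param spec a [split_spec()].
#' @return A list with `supervised_windows` elements `train`, `val`, `test`.
#' @export
chronological_split <- function(windows, spec = split_spec()) {
  wq_assert(inherits(spec, "split_spec"), "`spec` must be a split_spec")
  n <- n_samples(windows)
  n_train <- floor(spec$train_fraction * n)
  n_val <- floor(spec$val_fraction * n)
  list(
    train = subset_windows(windows, seq_len(n_train)),
    val = subset_windows(windows, seq_len(n_val) + n_train),
    test = subset_windows(windows,
                          seq.int(n_train + n_val + 1L, length.out = n - n_train - n_val))
  )
}
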
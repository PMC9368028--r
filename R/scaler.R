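#' Fit a per-indicator min-max scaler on training windows
#'
#' The scaler maps every indicator affinely onto \[0, 1\] over the range it
#' occupies in the *training* windows (inputs and targets pooled).  Fitting on
#' the training portion only keeps validation and test information out of the
#' preprocessing; out-of-range values are transformed by the same affine map,
#' never clipped, so the transform stays invertible.
#'
#' @param train_windows the training subset from [chronological_split()].
#' @return An object of class `wq_scaler` with per-indicator `min` and `max`.
#' @export
fit_scaler <- function(train_windows) {
  ind <- train_windows$indicator_names
  mn <- mx <- setNames(numeric(length(ind)), ind)
  for (i in seq_along(ind)) {
    vals <- c(train_windows$X[, , , i], train_windows$Y[, , i])
    mn[i] <- min(vals); mx[i] <- max(vals)
    if (!(mx[i] > mn[i])) {
      wq_stop(sprintf("indicator %s is constant on the training set; cannot scale",
                      ind[i]), "aquamtl_scaler_error")
    }
  }
  structure(list(min = mn, max = mx, method = "minmax"), class = "wq_scaler")
}

scale_values <- function(x, mn, mx, invert = FALSE) {
  if (invert) x * (mx - mn) + mn else (x - mn) / (mx - mn)
}

#' Apply or invert a fitted scaler on supervised windows
#'
#' @param windows a `supervised_windows` object.
#' @param scaler a [fit_scaler()] result.
#' @return The windows with `X` and `Y` transformed indicator-by-indicator.
#' @export
apply_scaler <- function(windows, scaler) {
  out <- windows
  for (i in seq_along(windows$indicator_names)) {
    nm <- windows$indicator_names[i]
    out$X[, , , i] <- scale_values(windows$X[, , , i], scaler$min[nm], scaler$max[nm])
    out$Y[, , i] <- scale_values(windows$Y[, , i], scaler$min[nm], scaler$max[nm])
  }
  out$scaled <- TRUE
  out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(windows, scaler) {
  out <- windows
  for (i in seq_along(windows$indicator_names)) {
    nm <- windows$indicator_names[i]
    out$X[, , , i] <- scale_values(windows$X[, , , i], scaler$min[nm], scaler$max[nm],
                                   invert = TRUE)
    out$Y[, , i] <- scale_values(windows$Y[, , i], scaler$min[nm], scaler$max[nm],
                                 invert = TRUE)
  }
  out$scaled <- FALSE
  out
}

# Invert a (sample x station) prediction matrix for one indicator.
invert_indicator <- function(mat, scaler, indicator) {
  scale_values(mat, scaler$min[[indicator]], scaler$max[[indicator]], invert = TRUE)
}
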
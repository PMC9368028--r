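#' Rectified linear unit
#'
#' `relu(x) = x` for positive entries and 0 otherwise, applied elementwise.
#'
#' @param x numeric vector, matrix or array.
#' @return `pmax(x, 0)` with the input's shape.
#' @export
relu <- function(x) {
  out <- pmax(x, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Fully connected layer
#'
#' Computes `z = W x + b`, optionally followed by [relu()].
#'
#' @param x numeric input vector (length = `ncol(W)`).
#' @param W weight matrix, one row per output unit.
#' @param b bias vector (length = `nrow(W)`).
#' @param activation apply ReLU to the affine output (default `TRUE`).
#' @return numeric output vector of length `nrow(W)`.
#' @export
dense_layer <- function(x, W, b, activation = TRUE) {
  W <- as.matrix(W)
  if (length(x) != ncol(W) || length(b) != nrow(W)) {
    wq_stop(sprintf("dense_layer dimension mismatch: x has %d, W is %dx%d, b has %d",
                    length(x), nrow(W), ncol(W), length(b)),
            "aquamtl_dim_error")
  }
  z <- drop(W %*% x) + b
  if (activation) relu(z) else z
}

#' Numerically stable softmax
#'
#' Exponentiates max-shifted logits and normalises them to a probability
#' vector, so arbitrarily large logits do not overflow.
#'
#' @param logits finite numeric vector.
#' @return probability vector of the same length, summing to 1.
#' @export
softmax <- function(logits) {
  wq_assert(all(is.finite(logits)), "softmax requires finite logits")
  e <- exp(logits - max(logits))
  e / sum(e)
}
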
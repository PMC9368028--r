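# Reverse-mode automatic differentiation on batched matrices.
#
# A tape records every operation of a forward pass; backward() walks the tape
# in reverse, accumulating gradients into each node.  Values are numeric
# matrices with one row per sample, so a whole minibatch flows through a
# single tape.  Parameters enter as leaf nodes; their accumulated gradients
# drive the optimiser.  The engine is deliberately small: it supports exactly
# the operations the sharing structures and tower layers need.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# y = x W' + b  (x: n x in, W: out x in, b: out)
ad_linear <- function(tape, x, W, b) {
  val <- x$value %*% t(W$value)
  val <- sweep(val, 2L, b$value, "+")
  ad_node(tape, val, function(g) {
    ad_accum(x, g %*% W$value)
    ad_accum(W, t(g) %*% x$value)
    ad_accum(b, colSums(g))
  })
}

ad_relu <- function(tape, x) {
  mask <- x$value > 0
  ad_node(tape, x$value * mask, function(g) ad_accum(x, g * mask))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, function(g) ad_accum(x, g * s * (1 - s)))
}

ad_tanh <- function(tape, x) {
  s <- tanh(x$value)
  ad_node(tape, s, function(g) ad_accum(x, g * (1 - s^2)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_cbind <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(tape, do.call(cbind, lapply(parts, `[[`, "value")), function(g) {
    for (j in seq_along(parts)) {
      ad_accum(parts[[j]], g[, starts[j]:ends[j], drop = FALSE])
    }
  })
}

ad_cols <- function(tape, x, idx) {
  nc <- ncol(x$value)
  ad_node(tape, x$value[, idx, drop = FALSE], function(g) {
    full <- matrix(0, nrow(g), nc)
    full[, idx] <- g
    ad_accum(x, full)
  })
}

# Row-wise softmax, numerically stabilised by max subtraction.
ad_softmax <- function(tape, x) {
  z <- x$value - apply(x$value, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(tape, p, function(g) {
    ad_accum(x, p * (g - rowSums(g * p)))
  })
}

# Scale the rows of h (n x d) by column j of the weight matrix w (n x k).
ad_rowscale <- function(tape, h, w, j) {
  wj <- w$value[, j]
  ad_node(tape, h$value * wj, function(g) {
    ad_accum(h, g * wj)
    gw <- matrix(0, nrow(g), ncol(w$value))
    gw[, j] <- rowSums(g * h$value)
    ad_accum(w, gw)
  })
}

# Sum over indicators of the mean squared error between prediction nodes and
# plain target matrices: the joint training loss (see mtl_loss()).
ad_joint_sq_loss <- function(tape, preds, targets) {
  total <- 0
  for (i in seq_along(preds)) {
    total <- total + mean((preds[[i]]$value - targets[[i]])^2)
  }
  ad_node(tape, total, function(g) {
    for (i in seq_along(preds)) {
      P <- preds[[i]]$value
      ad_accum(preds[[i]], g * 2 * (P - targets[[i]]) / length(P))
    }
  })
}

ad_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (id in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[id]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}
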
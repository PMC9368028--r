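#' Training configuration
#'
#' Defaults follow the study protocol: learning rate 0.001, 100 epochs,
#' minibatches of 5, Adam with its standard moment constants.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs full passes over the training windows (>= 1).
#' @param batch_size minibatch size (>= 1).
#' @param seed integer seed controlling shuffling (and any other randomness
#'   in the run); identical seed + data + config reproduce the run exactly.
#' @param checkpoint `"best_val"` returns the parameters with the lowest
#'   validation loss; `"final"` returns the last-epoch parameters.
#' @param beta1,beta2,epsilon Adam moment-decay and stabilisation constants.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100L, batch_size = 5L,
                         seed = 1L, checkpoint = c("best_val", "final"),
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  wq_assert(learning_rate > 0, "learning rate must be > 0", "aquamtl_config_error")
  wq_assert(epochs >= 1L, "epochs must be >= 1", "aquamtl_config_error")
  wq_assert(batch_size >= 1L, "batch size must be >= 1", "aquamtl_config_error")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint = match.arg(checkpoint),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

#' Joint multi-task training loss
#'
#' The per-sample loss sums the squared errors of all predicted indicators
#' and averages over samples (the printed training objective carries no
#' square root, so it is a summed squared error despite its RMSE label;
#' root-mean-square error is reported only at evaluation time).  Within each
#' indicator the squared error is averaged over stations, keeping the loss
#' scale independent of the station count.
#'
#' @param predictions,targets named lists (one entry per task) of equal-shape
#'   numeric matrices or vectors.
#' @return A single non-negative number:
#'   `sum over tasks of mean((target - prediction)^2)`.
#' @export
mtl_loss <- function(predictions, targets) {
  wq_assert(length(predictions) >= 1L, "empty prediction set", "aquamtl_empty_error")
  tasks <- names(predictions)
  wq_assert(!is.null(tasks) && all(tasks %in% names(targets)),
            "predictions and targets must share task names", "aquamtl_task_error")
  total <- 0
  for (t in tasks) {
    p <- predictions[[t]]; y <- targets[[t]]
    wq_assert(length(p) == length(y) && length(p) >= 1L,
              sprintf("shape mismatch or empty batch for task %s", t),
              "aquamtl_dim_error")
    total <- total + mean((y - p)^2)
  }
  total
}

loss_value <- function(model, Xlist, Ylist) {
  fp <- forward_pass(model, Xlist)
  mtl_loss(lapply(fp$preds, `[[`, "value"), Ylist)
}

# One forward + backward pass; returns loss value and per-layer gradients.
loss_and_grads <- function(model, Xlist, Ylist) {
  fp <- forward_pass(model, Xlist)
  loss <- ad_joint_sq_loss(fp$tape, fp$preds[model$config$tasks],
                           Ylist[model$config$tasks])
  ad_backward(fp$tape, loss)
  grads <- lapply(fp$param_nodes, function(nd) {
    list(W = if (is.null(nd$W$grad)) nd$W$value * 0 else nd$W$grad,
         b = if (is.null(nd$b$grad)) nd$b$value * 0 else nd$b$grad)
  })
  list(loss = loss$value, grads = grads)
}

adam_state <- function(params) {
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(params, grads, state, cfg, t) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; st <- state[[nm]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W -
      cfg$learning_rate * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      cfg$learning_rate * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

subset_xy <- function(Xlist, Ylist, idx) {
  list(X = lapply(Xlist, function(m) m[idx, , drop = FALSE]),
       Y = lapply(Ylist, function(m) m[idx, , drop = FALSE]))
}

#' Train a model with Adam on scaled supervised windows
#'
#' Runs the full epoch budget, shuffling the training windows each epoch
#' under the run seed, minimising [mtl_loss()] by minibatch Adam, and
#' recording the full-data training and validation losses after every epoch.
#'
#' @param model a [build_model()] result.
#' @param train_windows,val_windows scaled `supervised_windows` subsets from
#'   [chronological_split()] + [apply_scaler()].
#' @param config a [train_config()].
#' @return An object of class `wq_fit`: `model` (checkpoint chosen by
#'   `config$checkpoint`), `final_model` (last-epoch parameters), `history`
#'   (data frame of per-epoch `train_loss` / `val_loss`), `best_epoch` and
#'   the configs used.
#' @export
train_model <- function(model, train_windows, val_windows, config = train_config()) {
  wq_assert(inherits(config, "train_config"), "`config` must be a train_config")
  tasks <- model$config$tasks
  Xtr <- windows_to_inputs(train_windows, tasks)
  Ytr <- windows_to_targets(train_windows, tasks)
  Xva <- windows_to_inputs(val_windows, tasks)
  Yva <- windows_to_targets(val_windows, tasks)
  n <- nrow(Xtr[[1L]])
  wq_assert(n >= 1L, "no training samples", "aquamtl_empty_error")
  set.seed(config$seed)
  state <- adam_state(model$params)
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    batch_starts <- seq.int(1L, n, by = config$batch_size)
    for (bi in seq_along(batch_starts)) {
      idx <- perm[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
      batch <- subset_xy(Xtr, Ytr, idx)
      lg <- loss_and_grads(model, batch$X, batch$Y)
      if (!is.finite(lg$loss)) {
        wq_stop(sprintf("non-finite training loss at epoch %d, batch %d",
                        epoch, bi), "aquamtl_numeric_error")
      }
      step <- step + 1L
      upd <- adam_step(model$params, lg$grads, state, config, step)
      model$params <- upd$params
      state <- upd$state
    }
    tr_loss <- loss_value(model, Xtr, Ytr)
    va_loss <- if (nrow(Xva[[1L]]) > 0L) loss_value(model, Xva, Yva) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = va_loss))
    if (is.finite(va_loss) && va_loss < best$val) {
      best <- list(val = va_loss, params = model$params, epoch = epoch)
    }
  }
  final_model <- model
  if (config$checkpoint == "best_val" && is.finite(best$val)) {
    model$params <- best$params
  }
  structure(list(model = model, final_model = final_model, history = history,
                 best_epoch = best$epoch, steps = step, train_config = config,
                 structure_config = model$config),
            class = "wq_fit")
}

#' @export
print.wq_fit <- function(x, ...) {
  cat(sprintf("<wq_fit> structure=%s epochs=%d best_epoch=%d final val_loss=%.6g\n",
              x$structure_config$structure, nrow(x$history), x$best_epoch,
              tail(x$history$val_loss, 1L)))
  invisible(x)
}

#' Seed every random stream used by the package
#'
#' Model initialisation, epoch shuffling and the synthetic generator all draw
#' from R's global RNG (the generator re-seeds deterministic sub-streams from
#' its own config seed), so one call makes a whole run reproducible.
#'
#' @param seed integer seed.
#' @return The seed, invisibly.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Finite-difference check of the analytic gradients
#'
#' Compares every parameter's reverse-mode gradient of [mtl_loss()] against a
#' central finite difference.  The loss is piecewise smooth (ReLU), so two
#' kinds of coordinate are excluded and counted instead of compared: dead
#' directions where both gradients vanish, and kink coordinates where the
#' one-sided difference quotients disagree (the finite difference straddles a
#' ReLU boundary, e.g. a zero-initialised bias behind an inactive unit, and
#' no two-sided derivative exists).
#'
#' @param model a small [build_model()] result (finite differences cost two
#'   forward passes per parameter).
#' @param windows a scaled `supervised_windows` batch.
#' @param step finite-difference half-step (default 1e-5).
#' @param dead_tol threshold below which a coordinate counts as dead.
#' @param kink_tol relative disagreement between the one-sided quotients
#'   above which a coordinate counts as a kink.
#' @return A list with `max_rel_err`, `n_checked` and `n_skipped`.
#' @export
gradient_check <- function(model, windows, step = 1e-5, dead_tol = 1e-8,
                           kink_tol = 0.02) {
  tasks <- model$config$tasks
  Xlist <- windows_to_inputs(windows, tasks)
  Ylist <- windows_to_targets(windows, tasks)
  analytic <- loss_and_grads(model, Xlist, Ylist)$grads
  f0 <- loss_value(model, Xlist, Ylist)
  max_rel <- 0
  n_checked <- 0L
  n_skipped <- 0L
  for (nm in names(model$params)) {
    for (comp in c("W", "b")) {
      vals <- model$params[[nm]][[comp]]
      for (j in seq_along(vals)) {
        m2 <- model
        m2$params[[nm]][[comp]][j] <- vals[j] + step
        up <- loss_value(m2, Xlist, Ylist)
        m2$params[[nm]][[comp]][j] <- vals[j] - step
        dn <- loss_value(m2, Xlist, Ylist)
        num <- (up - dn) / (2 * step)
        ana <- analytic[[nm]][[comp]][j]
        denom <- max(abs(num), abs(ana))
        if (denom < dead_tol) {
          n_skipped <- n_skipped + 1L
          next
        }
        d_plus <- (up - f0) / step
        d_minus <- (f0 - dn) / step
        if (abs(d_plus - d_minus) / max(abs(d_plus), abs(d_minus), dead_tol) >
            kink_tol) {
          n_skipped <- n_skipped + 1L
          next
        }
        n_checked <- n_checked + 1L
        max_rel <- max(max_rel, abs(num - ana) / denom)
      }
    }
  }
  list(max_rel_err = max_rel, n_checked = n_checked, n_skipped = n_skipped)
}
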
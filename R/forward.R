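# Forward computations of the four parameter-sharing structures.
#
# Each structure consumes one flattened (lookback x station) input matrix per
# task and emits one (sample x station) prediction matrix per task.  All
# passes run on the autodiff tape so the same code path serves prediction and
# training.

# Flatten supervised windows into the per-task input matrices (columns ordered
# time-fastest within station) and target matrices.
windows_to_inputs <- function(windows, tasks) {
  n <- n_samples(windows)
  idx <- match(tasks, windows$indicator_names)
  if (anyNA(idx)) {
    wq_stop(sprintf("unknown indicator(s): %s",
                    paste(tasks[is.na(idx)], collapse = ", ")),
            "aquamtl_task_error")
  }
  X <- lapply(idx, function(i) matrix(windows$X[, , , i], nrow = n))
  names(X) <- tasks
  X
}

windows_to_targets <- function(windows, tasks) {
  n <- n_samples(windows)
  idx <- match(tasks, windows$indicator_names)
  Y <- lapply(idx, function(i) matrix(windows$Y[, , i], nrow = n))
  names(Y) <- tasks
  Y
}

as_input_list <- function(model, data) {
  tasks <- model$config$tasks
  if (inherits(data, "supervised_windows")) return(windows_to_inputs(data, tasks))
  wq_assert(is.list(data), "inputs must be supervised_windows or a named list of matrices")
  missing <- setdiff(tasks, names(data))
  if (length(missing) > 0) {
    wq_stop(sprintf("inputs missing task(s): %s", paste(missing, collapse = ", ")),
            "aquamtl_task_error")
  }
  lapply(setNames(tasks, tasks), function(t) {
    m <- data[[t]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  })
}

ad_dense <- function(tape, x, layer_nodes, activation = TRUE) {
  z <- ad_linear(tape, x, layer_nodes$W, layer_nodes$b)
  if (activation) ad_relu(tape, z) else z
}

ad_one_minus <- function(tape, x) {
  ad_node(tape, 1 - x$value, function(g) ad_accum(x, -g))
}

ad_scale_const <- function(tape, x, k) {
  ad_node(tape, x$value * k, function(g) ad_accum(x, g * k))
}

ad_rowdot <- function(tape, a, b) {
  ad_node(tape, matrix(rowSums(a$value * b$value), ncol = 1L), function(g) {
    gv <- as.vector(g)
    ad_accum(a, gv * b$value)
    ad_accum(b, gv * a$value)
  })
}

seq_slices <- function(tape, v, L, D) {
  lapply(seq_len(L), function(t) ad_cols(tape, v, ((t - 1L) * D + 1L):(t * D)))
}

ad_tower <- function(tape, v, pn, cfg, task, n_stations) {
  tname <- function(s) sprintf("tw_%s_%s", task, s)
  if (cfg$tower_type == "mlp") {
    h <- v
    for (l in seq_len(cfg$tower_depth[[task]])) {
      h <- ad_dense(tape, h, pn[[sprintf("tw_%s_%d", task, l)]])
    }
    return(h)
  }
  sh <- tower_seq_shape(ncol(v$value))
  L <- sh[1L]; D <- sh[2L]
  xs <- seq_slices(tape, v, L, D)
  n <- nrow(v$value)
  if (cfg$tower_type == "lstm") {
    h <- ad_leaf(tape, matrix(0, n, D))
    cc <- ad_leaf(tape, matrix(0, n, D))
    for (t in seq_len(L)) {
      z <- ad_add(tape,
                  ad_linear(tape, xs[[t]], pn[[tname("lstm_x")]]$W, pn[[tname("lstm_x")]]$b),
                  ad_linear(tape, h, pn[[tname("lstm_h")]]$W, pn[[tname("lstm_h")]]$b))
      i <- ad_sigmoid(tape, ad_cols(tape, z, 1:D))
      f <- ad_sigmoid(tape, ad_cols(tape, z, (D + 1L):(2L * D)))
      g <- ad_tanh(tape, ad_cols(tape, z, (2L * D + 1L):(3L * D)))
      o <- ad_sigmoid(tape, ad_cols(tape, z, (3L * D + 1L):(4L * D)))
      cc <- ad_add(tape, ad_mul(tape, f, cc), ad_mul(tape, i, g))
      h <- ad_mul(tape, o, ad_tanh(tape, cc))
    }
    return(ad_dense(tape, h, pn[[tname("out")]]))
  }
  if (cfg$tower_type == "gru") {
    h <- ad_leaf(tape, matrix(0, n, D))
    for (t in seq_len(L)) {
      gx <- ad_linear(tape, xs[[t]], pn[[tname("gru_x")]]$W, pn[[tname("gru_x")]]$b)
      gh <- ad_linear(tape, h, pn[[tname("gru_h")]]$W, pn[[tname("gru_h")]]$b)
      r <- ad_sigmoid(tape, ad_add(tape, ad_cols(tape, gx, 1:D), ad_cols(tape, gh, 1:D)))
      zz <- ad_sigmoid(tape, ad_add(tape, ad_cols(tape, gx, (D + 1L):(2L * D)),
                                    ad_cols(tape, gh, (D + 1L):(2L * D))))
      nn <- ad_tanh(tape, ad_add(tape, ad_cols(tape, gx, (2L * D + 1L):(3L * D)),
                                 ad_mul(tape, r, ad_cols(tape, gh, (2L * D + 1L):(3L * D)))))
      h <- ad_add(tape, ad_mul(tape, ad_one_minus(tape, zz), nn), ad_mul(tape, zz, h))
    }
    return(ad_dense(tape, h, pn[[tname("out")]]))
  }
  if (cfg$tower_type == "cnn") {
    zero <- ad_leaf(tape, matrix(0, n, D))
    feats <- lapply(seq_len(L), function(p) {
      window <- ad_cbind(tape, list(
        if (p > 1L) xs[[p - 1L]] else zero,
        xs[[p]],
        if (p < L) xs[[p + 1L]] else zero
      ))
      ad_dense(tape, window, pn[[tname("conv")]])
    })
    return(ad_dense(tape, ad_cbind(tape, feats), pn[[tname("out")]]))
  }
  if (cfg$tower_type == "attention") {
    Q <- lapply(xs, function(x) ad_dense(tape, x, pn[[tname("attq")]], activation = FALSE))
    K <- lapply(xs, function(x) ad_dense(tape, x, pn[[tname("attk")]], activation = FALSE))
    V <- lapply(xs, function(x) ad_dense(tape, x, pn[[tname("attv")]], activation = FALSE))
    outs <- lapply(seq_len(L), function(t) {
      scores <- ad_cbind(tape, lapply(seq_len(L), function(u) {
        ad_scale_const(tape, ad_rowdot(tape, Q[[t]], K[[u]]), 1 / sqrt(D))
      }))
      a <- ad_softmax(tape, scores)
      fused <- ad_rowscale(tape, V[[1L]], a, 1L)
      if (L > 1L) {
        for (u in 2L:L) fused <- ad_add(tape, fused, ad_rowscale(tape, V[[u]], a, u))
      }
      fused
    })
    return(ad_dense(tape, ad_cbind(tape, outs), pn[[tname("out")]]))
  }
  wq_stop(sprintf("unknown tower type %s", cfg$tower_type), "aquamtl_config_error")
}

# Full forward pass on a fresh tape.  Returns the tape, prediction nodes,
# parameter nodes (for gradient collection) and gate-weight matrices.
forward_pass <- function(model, Xlist) {
  cfg <- model$config
  tasks <- cfg$tasks
  S <- model$dims$n_stations
  tape <- ad_tape()
  pn <- lapply(model$params, function(l) {
    list(W = ad_leaf(tape, l$W), b = ad_leaf(tape, l$b))
  })
  xin <- lapply(setNames(tasks, tasks), function(t) ad_leaf(tape, Xlist[[t]]))
  gates <- list()
  preds <- list()
  if (cfg$structure == "linear_baseline") {
    for (t in tasks) preds[[t]] <- ad_dense(tape, xin[[t]], pn[[paste0("lin_", t)]],
                                            activation = FALSE)
    return(list(tape = tape, preds = preds, param_nodes = pn, gates = gates))
  }
  outs <- lapply(setNames(tasks, tasks), function(t) {
    ad_dense(tape, xin[[t]], pn[[paste0("enc_", t)]])
  })
  hidden_shared <- NULL
  if (cfg$structure %in% c("soft", "gh")) {
    joint <- ad_cbind(tape, unname(xin))
    hidden_shared <- ad_dense(tape, ad_dense(tape, joint, pn$hid_1), pn$hid_2)
  }
  for (t in tasks) {
    v <- switch(
      cfg$structure,
      hard = ad_cbind(tape, unname(outs)),
      soft = ad_cbind(tape, list(outs[[t]], hidden_shared)),
      single_task = outs[[t]],
      gate = {
        logits <- ad_dense(tape, ad_cbind(tape, unname(outs)),
                           pn[[paste0("gate_", t)]], activation = FALSE)
        w <- ad_softmax(tape, logits)
        gates[[t]] <- w$value
        hiddens <- lapply(tasks, function(j) ad_dense(tape, outs[[j]], pn$maph))
        fused <- ad_rowscale(tape, hiddens[[1L]], w, 1L)
        if (length(tasks) > 1L) {
          for (j in 2L:length(tasks)) {
            fused <- ad_add(tape, fused, ad_rowscale(tape, hiddens[[j]], w, j))
          }
        }
        fused
      },
      gh = {
        comb <- ad_cbind(tape, list(outs[[t]], hidden_shared))
        logits <- ad_dense(tape, comb, pn[[paste0("gate_", t)]], activation = FALSE)
        w <- ad_softmax(tape, logits)
        gates[[t]] <- w$value
        hidden_t <- ad_dense(tape, comb, pn$maph)
        if (identical(cfg$gh_fusion, "concat") && !isTRUE(cfg$gh_literal_fusion)) {
          ad_cbind(tape, list(ad_rowscale(tape, hidden_t, w, 1L),
                              ad_rowscale(tape, hidden_shared, w, 2L)))
        } else {
          other <- if (isTRUE(cfg$gh_literal_fusion)) hidden_t else {
            ad_dense(tape, hidden_shared, pn$projh, activation = FALSE)
          }
          ad_add(tape, ad_rowscale(tape, hidden_t, w, 1L),
                 ad_rowscale(tape, other, w, 2L))
        }
      }
    )
    preds[[t]] <- ad_tower(tape, v, pn, cfg, t, S)
  }
  list(tape = tape, preds = preds, param_nodes = pn, gates = gates)
}

check_structure <- function(model, expected) {
  if (!identical(model$config$structure, expected)) {
    wq_stop(sprintf("model was built for structure '%s', not '%s'",
                    model$config$structure, expected), "aquamtl_config_error")
  }
}

forward_values <- function(model, data) {
  fp <- forward_pass(model, as_input_list(model, data))
  for (t in names(fp$preds)) {
    if (!all(is.finite(fp$preds[[t]]$value))) {
      wq_stop(sprintf("non-finite activations in task %s", t), "aquamtl_numeric_error")
    }
  }
  list(predictions = lapply(fp$preds, `[[`, "value"), gate_weights = fp$gates)
}

#' Forward pass of the hard parameter-sharing structure
#'
#' All task encodings are concatenated into one shared representation that
#' every tower consumes.
#'
#' @param model a [build_model()] result with the matching structure.
#' @param data a scaled `supervised_windows` object or a named list with one
#'   (sample x lookback*station) matrix per task.
#' @return A list with `predictions` (one (sample x station) matrix per task)
#'   and `gate_weights` (per-task softmax weight matrices, for the gated
#'   structures; empty otherwise).
#' @export
forward_hard <- function(model, data) {
  check_structure(model, "hard")
  forward_values(model, data)
}

#' Forward pass of the soft parameter-sharing structure
#'
#' Each tower consumes its task's own encoding concatenated with a hidden
#' vector learned jointly from all tasks' inputs.
#'
#' @inheritParams forward_hard
#' @inherit forward_hard return
#' @export
forward_soft <- function(model, data) {
  check_structure(model, "soft")
  forward_values(model, data)
}

#' Forward pass of the gated parameter-sharing structure
#'
#' A per-task softmax gate over all indicators weights a shared mapping of
#' each indicator's encoding; the weighted sum feeds the task tower.
#'
#' @inheritParams forward_hard
#' @inherit forward_hard return
#' @export
forward_gate <- function(model, data) {
  check_structure(model, "gate")
  forward_values(model, data)
}

#' Forward pass of the gated-hidden parameter-sharing structure
#'
#' A two-layer shared hidden block summarises all tasks' inputs; each task's
#' two-way softmax gate fuses its own mapped representation with a projection
#' of the shared hidden vector before the tower.
#'
#' @inheritParams forward_hard
#' @inherit forward_hard return
#' @export
forward_gh <- function(model, data) {
  check_structure(model, "gh")
  forward_values(model, data)
}

#' Per-indicator encoder outputs
#'
#' Applies each task's own dense + ReLU encoder to its flattened input
#' window.  Encoders never share weights across indicators.
#'
#' @inheritParams forward_hard
#' @return Named list of (sample x hidden_width) encoding matrices.
#' @export
encode_indicators <- function(model, data) {
  wq_assert(model$config$structure != "linear_baseline",
            "the linear baseline has no encoders")
  Xlist <- as_input_list(model, data)
  tape <- ad_tape()
  out <- lapply(setNames(model$config$tasks, model$config$tasks), function(t) {
    l <- model$params[[paste0("enc_", t)]]
    x <- ad_leaf(tape, Xlist[[t]])
    ad_dense(tape, x, list(W = ad_leaf(tape, l$W), b = ad_leaf(tape, l$b)))$value
  })
  out
}

#' Run one task's tower on a fusion vector
#'
#' @param v numeric fusion vector (or matrix with one row per sample) of the
#'   tower's input width.
#' @param model a `wq_model` whose structure has towers.
#' @param task which task's tower to run.
#' @return The tower output: a station-length vector (or sample x station
#'   matrix for matrix input).
#' @export
tower_forward <- function(v, model, task) {
  wq_assert(task %in% model$config$tasks, "unknown task")
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, nrow = 1L)
  tape <- ad_tape()
  pn <- lapply(model$params, function(l) {
    list(W = ad_leaf(tape, l$W), b = ad_leaf(tape, l$b))
  })
  out <- ad_tower(tape, ad_leaf(tape, v), pn, model$config, task,
                  model$dims$n_stations)$value
  if (vec_in) drop(out) else out
}

#' Predict with a trained model
#'
#' @param object a `wq_model`.
#' @param windows scaled `supervised_windows` (or a named input-matrix list).
#' @param scaler optional [fit_scaler()] result; when given, predictions are
#'   mapped back to the original measurement scale.
#' @param ... unused.
#' @return Named list of (sample x station) prediction matrices per task.
#' @export
predict.wq_model <- function(object, windows, scaler = NULL, ...) {
  preds <- forward_values(object, windows)$predictions
  if (!is.null(scaler)) {
    preds <- lapply(setNames(names(preds), names(preds)), function(t) {
      invert_indicator(preds[[t]], scaler, t)
    })
  }
  preds
}
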
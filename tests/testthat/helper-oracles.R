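# Independent straight-line oracles for the tests.  These re-derive every
# quantity with plain loops and vector arithmetic, sharing no code with the
# package's tape-based forward passes.

oracle_dense <- function(x, layer, act = TRUE) {
  z <- as.vector(layer$W %*% x) + layer$b
  if (act) ifelse(z > 0, z, 0) else z
}

oracle_softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

oracle_tower <- function(model, task, v) {
  for (l in seq_len(model$config$tower_depth[[task]])) {
    v <- oracle_dense(v, model$params[[sprintf("tw_%s_%d", task, l)]])
  }
  v
}

# Each oracle takes a named list of single-sample input vectors and returns
# the per-task prediction vectors, transcribing the structure equations.
oracle_forward <- function(model, xl) {
  p <- model$params
  tasks <- model$config$tasks
  outs <- lapply(tasks, function(t) oracle_dense(xl[[t]], p[[paste0("enc_", t)]]))
  names(outs) <- tasks
  hidden_shared <- NULL
  if (model$config$structure %in% c("soft", "gh")) {
    joint <- unlist(xl[tasks], use.names = FALSE)
    hidden_shared <- oracle_dense(oracle_dense(joint, p$hid_1), p$hid_2)
  }
  preds <- list()
  gates <- list()
  for (t in tasks) {
    v <- switch(
      model$config$structure,
      hard = unlist(outs, use.names = FALSE),
      soft = c(outs[[t]], hidden_shared),
      single_task = outs[[t]],
      gate = {
        w <- oracle_softmax(oracle_dense(unlist(outs, use.names = FALSE),
                                         p[[paste0("gate_", t)]], act = FALSE))
        gates[[t]] <- w
        acc <- 0
        for (j in seq_along(tasks)) {
          acc <- acc + w[j] * oracle_dense(outs[[tasks[j]]], p$maph)
        }
        acc
      },
      gh = {
        comb <- c(outs[[t]], hidden_shared)
        w <- oracle_softmax(oracle_dense(comb, p[[paste0("gate_", t)]], act = FALSE))
        gates[[t]] <- w
        ht <- oracle_dense(comb, p$maph)
        if (isTRUE(model$config$gh_literal_fusion)) {
          w[1] * ht + w[2] * ht
        } else if (identical(model$config$gh_fusion, "concat")) {
          c(w[1] * ht, w[2] * hidden_shared)
        } else {
          w[1] * ht + w[2] * oracle_dense(hidden_shared, p$projh, act = FALSE)
        }
      }
    )
    preds[[t]] <- oracle_tower(model, t, v)
  }
  list(preds = preds, gates = gates)
}

# Brute-force metric implementations (explicit loops).
oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}
oracle_mae <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - yhat[i])
  s / length(y)
}
oracle_mape <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs((y[i] - yhat[i]) / y[i])
  s / length(y)
}

# Brute-force joint loss: sum over tasks of mean squared error.
oracle_mtl_loss <- function(preds, targets) {
  total <- 0
  for (t in names(preds)) {
    d <- as.vector(targets[[t]]) - as.vector(preds[[t]])
    total <- total + sum(d^2) / length(d)
  }
  total
}

# A small deterministic panel with linearly rising values, handy as a fully
# observed fixture.
ramp_panel <- function(n_stations = 2, n_weeks = 30) {
  v <- array(0, dim = c(n_stations, n_weeks, 4))
  for (s in seq_len(n_stations)) {
    for (i in 1:4) v[s, , i] <- seq_len(n_weeks) + 10 * i + s
  }
  indicator_panel(v, as.Date("2013-01-07") + 7 * (seq_len(n_weeks) - 1))
}

# Identity-like scaler (unit range) for tests that bypass fitting.
unit_scaler <- function(indicators = c("pH", "DO", "CODMn", "NH3N")) {
  structure(list(min = setNames(rep(0, length(indicators)), indicators),
                 max = setNames(rep(1, length(indicators)), indicators),
                 method = "minmax"),
            class = "wq_scaler")
}

# Small random model + matching random single-sample inputs.
tiny_model <- function(structure, width = 3, lookback = 2, stations = 2,
                       tower_type = "mlp", seed = 42, tasks = c("pH", "DO", "CODMn", "NH3N")) {
  cfg <- structure_config(structure, tower_type = tower_type, tasks = tasks,
                          hidden_width = width)
  build_model(cfg, lookback, stations, seed = seed)
}

random_inputs <- function(model, n = 1) {
  tasks <- model$config$tasks
  d <- model$dims$in_dim
  lapply(setNames(tasks, tasks), function(t) {
    matrix(rnorm(n * d), nrow = n)
  })
}

# Scaled train/val/test windows for a small synthetic panel.
scaled_splits <- function(panel, lookback = 10, horizon = 1) {
  w <- make_windows(panel, lookback, horizon)
  sp <- chronological_split(w)
  sc <- fit_scaler(sp$train)
  list(train = apply_scaler(sp$train, sc), val = apply_scaler(sp$val, sc),
       test = apply_scaler(sp$test, sc), scaler = sc, windows = w)
}
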
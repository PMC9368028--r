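#' Model structure configuration
#'
#' Describes which parameter-sharing structure to build, the tower type, the
#' task subset and the layer sizes.  The four sharing structures are:
#' `hard` (towers consume one concatenated shared representation), `soft`
#' (each task's encoding is concatenated with a jointly learned hidden
#' vector), `gate` (softmax task gates fuse the per-indicator
#' representations) and `gh` (gates fuse a task representation with the
#' shared hidden vector).  `single_task` builds fully independent per-task
#' networks and `linear_baseline` one affine map per task.
#'
#' @param structure one of `"hard"`, `"soft"`, `"gate"`, `"gh"`,
#'   `"single_task"`, `"linear_baseline"`.
#' @param tower_type task-head type: `"mlp"` (default), `"lstm"`, `"gru"`,
#'   `"cnn"` or `"attention"`.
#' @param tasks indicators to predict jointly (non-empty subset of the
#'   panel's indicators).
#' @param hidden_width width of encoder/hidden/fusion layers (default 64).
#' @param tower_depth named per-task MLP tower depths; defaults to
#'   pH 3, DO 3, CODMn 2, NH3N 2 (tasks without an entry get depth 2).
#' @param gh_fusion how the gated-hidden structure fuses the two gated
#'   branches: `"concat"` (default) feeds the tower the blockwise-gated
#'   concatenation `[w1 * hidden_t, w2 * hidden_shared]`; `"project_add"`
#'   adds the gated task representation to a gated dense projection of the
#'   shared hidden vector.
#' @param gh_literal_fusion if `TRUE` the gated-hidden fusion uses the
#'   printed form in which both gate branches scale the task representation
#'   (the gate weights then cancel); kept for comparison.
#' @return An object of class `structure_config`.
#' @export
structure_config <- function(structure = c("hard", "soft", "gate", "gh",
                                           "single_task", "linear_baseline"),
                             tower_type = c("mlp", "lstm", "gru", "cnn", "attention"),
                             tasks = WQ_INDICATORS,
                             hidden_width = 64L,
                             tower_depth = c(pH = 3L, DO = 3L, CODMn = 2L, NH3N = 2L),
                             gh_fusion = c("concat", "project_add"),
                             gh_literal_fusion = FALSE) {
  gh_fusion <- match.arg(gh_fusion)
  structure_tag <- match.arg(structure)
  tower_type <- match.arg(tower_type)
  wq_assert(length(tasks) >= 1L && !anyDuplicated(tasks),
            "task subset must be non-empty with unique names", "aquamtl_config_error")
  wq_assert(hidden_width >= 1L, "hidden width must be >= 1", "aquamtl_config_error")
  depth <- setNames(rep(2L, length(tasks)), tasks)
  known <- intersect(tasks, names(tower_depth))
  depth[known] <- as.integer(tower_depth[known])
  wq_assert(all(depth >= 1L), "tower depths must be >= 1", "aquamtl_config_error")
  structure(list(structure = structure_tag, tower_type = tower_type,
                 tasks = tasks, hidden_width = as.integer(hidden_width),
                 tower_depth = depth, gh_fusion = gh_fusion,
                 gh_literal_fusion = gh_literal_fusion),
            class = "structure_config")
}

init_layer <- function(n_out, n_in) {
  lim <- sqrt(6 / n_in)
  # biases start at a small positive value so ReLU units begin active
  # (a zero-initialised unit behind an inactive layer sits exactly on the
  # ReLU kink and can never receive gradient)
  list(W = matrix(runif(n_out * n_in, -lim, lim), n_out, n_in),
       b = rep(0.01, n_out))
}

# Sequence shape used by the recurrent/convolutional/attention towers: the
# fusion vector is folded into (seq_len, features-per-step).
tower_seq_shape <- function(width) {
  seq_len <- if (width %% 4L == 0L) 4L else if (width %% 2L == 0L) 2L else 1L
  c(seq_len, width %/% seq_len)
}

tower_layer_names <- function(cfg, task) {
  d <- cfg$tower_depth[[task]]
  switch(cfg$tower_type,
         mlp = sprintf("tw_%s_%d", task, seq_len(d)),
         lstm = sprintf("tw_%s_%s", task, c("lstm_x", "lstm_h", "out")),
         gru = sprintf("tw_%s_%s", task, c("gru_x", "gru_h", "out")),
         cnn = sprintf("tw_%s_%s", task, c("conv", "out")),
         attention = sprintf("tw_%s_%s", task, c("attq", "attk", "attv", "out")))
}

build_tower_params <- function(cfg, task, tower_in, n_stations) {
  H <- cfg$hidden_width
  out <- list()
  if (cfg$tower_type == "mlp") {
    d <- cfg$tower_depth[[task]]
    widths_in <- c(tower_in, rep(H, d - 1L))
    widths_out <- c(rep(H, d - 1L), n_stations)
    for (l in seq_len(d)) {
      out[[sprintf("tw_%s_%d", task, l)]] <- init_layer(widths_out[l], widths_in[l])
    }
  } else {
    sh <- tower_seq_shape(tower_in)
    L <- sh[1L]; D <- sh[2L]
    if (cfg$tower_type == "lstm") {
      out[[sprintf("tw_%s_lstm_x", task)]] <- init_layer(4L * D, D)
      out[[sprintf("tw_%s_lstm_h", task)]] <- init_layer(4L * D, D)
      out[[sprintf("tw_%s_out", task)]] <- init_layer(n_stations, D)
    } else if (cfg$tower_type == "gru") {
      out[[sprintf("tw_%s_gru_x", task)]] <- init_layer(3L * D, D)
      out[[sprintf("tw_%s_gru_h", task)]] <- init_layer(3L * D, D)
      out[[sprintf("tw_%s_out", task)]] <- init_layer(n_stations, D)
    } else if (cfg$tower_type == "cnn") {
      out[[sprintf("tw_%s_conv", task)]] <- init_layer(D, 3L * D)
      out[[sprintf("tw_%s_out", task)]] <- init_layer(n_stations, L * D)
    } else if (cfg$tower_type == "attention") {
      for (nm in c("attq", "attk", "attv")) {
        out[[sprintf("tw_%s_%s", task, nm)]] <- init_layer(D, D)
      }
      out[[sprintf("tw_%s_out", task)]] <- init_layer(n_stations, L * D)
    }
  }
  out
}

# Width of the vector each tower consumes, per sharing structure.
tower_input_width <- function(cfg) {
  H <- cfg$hidden_width
  nt <- length(cfg$tasks)
  switch(cfg$structure,
         hard = nt * H,
         soft = 2L * H,
         gate = H,
         gh = if (identical(cfg$gh_fusion, "concat") &&
                  !isTRUE(cfg$gh_literal_fusion)) 2L * H else H,
         single_task = H,
         linear_baseline = NA_integer_)
}

#' Allocate model parameters for a sharing structure
#'
#' Weights use uniform He-style fan-in initialisation
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`); biases start at zero.  With the
#' same `seed` the initial parameters are identical across calls.
#'
#' @param config a [structure_config()].
#' @param lookback input window length in weeks.
#' @param n_stations stations predicted jointly (each task's input is the
#'   flattened lookback-by-station block; its output is one value per station).
#' @param seed optional integer seed for the initial draw.
#' @return An object of class `wq_model` holding `config`, `dims` and the
#'   named parameter list (`W`/`b` pairs per layer).
#' @export
build_model <- function(config, lookback, n_stations, seed = NULL) {
  wq_assert(inherits(config, "structure_config"), "`config` must be a structure_config")
  if (!is.null(seed)) set.seed(seed)
  H <- config$hidden_width
  nt <- length(config$tasks)
  in_dim <- as.integer(lookback) * as.integer(n_stations)
  wq_assert(in_dim >= 1L, "lookback and n_stations must be positive")
  params <- list()
  if (config$structure == "linear_baseline") {
    for (t in config$tasks) params[[paste0("lin_", t)]] <- init_layer(n_stations, in_dim)
  } else {
    for (t in config$tasks) params[[paste0("enc_", t)]] <- init_layer(H, in_dim)
    if (config$structure %in% c("soft", "gh")) {
      params$hid_1 <- init_layer(H, nt * in_dim)
      params$hid_2 <- init_layer(H, H)
    }
    if (config$structure == "gate") {
      for (t in config$tasks) params[[paste0("gate_", t)]] <- init_layer(nt, nt * H)
      params$maph <- init_layer(H, H)
    }
    if (config$structure == "gh") {
      for (t in config$tasks) params[[paste0("gate_", t)]] <- init_layer(2L, 2L * H)
      params$maph <- init_layer(H, 2L * H)
      if (identical(config$gh_fusion, "project_add") &&
          !isTRUE(config$gh_literal_fusion)) {
        params$projh <- init_layer(H, H)
      }
    }
    tower_in <- tower_input_width(config)
    for (t in config$tasks) {
      params <- c(params, build_tower_params(config, t, tower_in, n_stations))
    }
  }
  structure(list(config = config,
                 dims = list(lookback = as.integer(lookback),
                             n_stations = as.integer(n_stations),
                             in_dim = in_dim,
                             tower_in = tower_input_width(config)),
                 params = params),
            class = "wq_model")
}

#' Initialise each output head to predict the mean training target
#'
#' Zeroes the final layer's weights and sets its bias to the station-wise
#' mean of the task's training targets, so every model starts by predicting
#' the training mean.  With a ReLU output head this guarantees the output
#' units begin active (an output unit whose pre-activation is negative for
#' all inputs receives no gradient and can never recover), and it removes
#' the initial phase in which the biases crawl up to the target scale.
#' Zeroing the last layer's weights costs nothing: their gradient depends
#' only on the incoming activations, so they move immediately.
#'
#' @param model a freshly built `wq_model`.
#' @param train_windows the training `supervised_windows` (scaled if training
#'   will be).
#' @return The model with re-initialised output heads.
#' @export
init_output_bias <- function(model, train_windows) {
  Y <- windows_to_targets(train_windows, model$config$tasks)
  for (t in model$config$tasks) {
    nm <- if (model$config$structure == "linear_baseline") {
      paste0("lin_", t)
    } else if (model$config$tower_type == "mlp") {
      sprintf("tw_%s_%d", t, model$config$tower_depth[[t]])
    } else {
      sprintf("tw_%s_out", t)
    }
    model$params[[nm]]$W[] <- 0
    model$params[[nm]]$b <- colMeans(Y[[t]])
  }
  model
}

#' Total trainable parameter count
#' @param model a [build_model()] result.
#' @return integer number of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.wq_model <- function(x, ...) {
  cat(sprintf("<wq_model> structure=%s tower=%s tasks=%s width=%d params=%d\n",
              x$config$structure, x$config$tower_type,
              paste(x$config$tasks, collapse = ","),
              x$config$hidden_width, n_params(x)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON: the structure configuration plus every named
#' parameter array at full precision, so a save/load round-trip is exact.
#'
#' @param model a `wq_model`.
#' @param path file path for the checkpoint.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` a `wq_model`.
#' @export
save_checkpoint <- function(model, path) {
  # doubles are serialised as 17-significant-digit strings so the
  # JSON round trip is bit-exact
  cfg_out <- unclass(model$config)
  cfg_out$tower_depth <- as.list(cfg_out$tower_depth)  # keep task names in JSON
  payload <- list(
    config = cfg_out,
    dims = model$dims,
    params = lapply(model$params, function(l) {
      list(W = sprintf("%.17g", as.vector(l$W)), dim = dim(l$W),
           b = sprintf("%.17g", l$b))
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- structure_config(
    structure = payload$config$structure,
    tower_type = payload$config$tower_type,
    tasks = payload$config$tasks,
    hidden_width = payload$config$hidden_width,
    tower_depth = unlist(payload$config$tower_depth),
    gh_fusion = payload$config$gh_fusion %||% "concat",
    gh_literal_fusion = isTRUE(payload$config$gh_literal_fusion)
  )
  params <- lapply(payload$params, function(l) {
    list(W = matrix(as.numeric(l$W), l$dim[1L], l$dim[2L]),
         b = as.numeric(l$b))
  })
  structure(list(config = cfg,
                 dims = list(lookback = payload$dims$lookback,
                             n_stations = payload$dims$n_stations,
                             in_dim = payload$dims$in_dim,
                             tower_in = payload$dims$tower_in),
                 params = params),
            class = "wq_model")
}
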
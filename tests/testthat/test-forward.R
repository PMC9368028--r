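forwarders <- list(hard = forward_hard, soft = forward_soft,
                   gate = forward_gate, gh = forward_gh)

test_that("every sharing structure matches its straight-line transcription", {
  set.seed(101)
  for (s in names(forwarders)) {
    m <- tiny_model(s, width = 3, lookback = 2, stations = 2, seed = 31)
    X <- random_inputs(m, n = 4)
    got <- forwarders[[s]](m, X)
    for (k in 1:4) {
      xk <- lapply(X, function(mat) mat[k, ])
      want <- oracle_forward(m, xk)
      for (t in m$config$tasks) {
        expect_equal(got$predictions[[t]][k, ], want$preds[[t]],
                     tolerance = 1e-9)
      }
      for (t in names(want$gates)) {
        expect_equal(got$gate_weights[[t]][k, ], want$gates[[t]],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the alternative gated-hidden fusion variants match their transcriptions", {
  set.seed(102)
  for (variant in list(list(gh_literal_fusion = TRUE),
                       list(gh_fusion = "project_add"))) {
    cfg <- do.call(structure_config,
                   c(list("gh", hidden_width = 3), variant))
    m <- build_model(cfg, 2, 2, seed = 77)
    X <- random_inputs(m, n = 2)
    got <- forward_gh(m, X)
    for (k in 1:2) {
      want <- oracle_forward(m, lapply(X, function(mat) mat[k, ]))
      for (t in cfg$tasks) {
        expect_equal(got$predictions[[t]][k, ], want$preds[[t]], tolerance = 1e-9)
      }
    }
  }
})

test_that("gate weight vectors are positive and sum to one on random inputs", {
  set.seed(103)
  for (s in c("gate", "gh")) {
    m <- tiny_model(s, width = 3, lookback = 2, stations = 2, seed = 55)
    X <- random_inputs(m, n = 1000)
    got <- forwarders[[s]](m, X)
    for (t in m$config$tasks) {
      w <- got$gate_weights[[t]]
      expect_equal(ncol(w), if (s == "gate") 4L else 2L)
      expect_true(all(w > 0))
      expect_true(all(abs(rowSums(w) - 1) < 1e-6))
    }
  }
})

test_that("zeroed gate layers give uniform weights and average fusion", {
  set.seed(104)
  m <- tiny_model("gate", width = 3, lookback = 2, stations = 2, seed = 9)
  for (t in m$config$tasks) {
    m$params[[paste0("gate_", t)]]$W[] <- 0
    m$params[[paste0("gate_", t)]]$b[] <- 0
  }
  X <- random_inputs(m, n = 5)
  got <- forward_gate(m, X)
  expect_true(all(abs(got$gate_weights$pH - 0.25) < 1e-12))
  # brute-force average-fusion model: mean of the mapped encodings
  outs <- encode_indicators(m, X)
  hid <- lapply(outs, function(o) {
    t(apply(o, 1, function(v) oracle_dense(v, m$params$maph)))
  })
  fused <- Reduce(`+`, hid) / 4
  for (t in m$config$tasks) {
    want <- t(apply(fused, 1, function(v) oracle_tower(m, t, v)))
    expect_equal(got$predictions[[t]], want, tolerance = 1e-9)
  }
})

test_that("saturated gate logits select a single branch", {
  set.seed(105)
  m <- tiny_model("gate", width = 3, lookback = 2, stations = 2, seed = 10)
  m$params$gate_DO$W[] <- 0
  m$params$gate_DO$b <- c(40, -40, -40, -40)
  X <- random_inputs(m, n = 3)
  got <- forward_gate(m, X)
  outs <- encode_indicators(m, X)
  hid_ph <- t(apply(outs$pH, 1, function(v) oracle_dense(v, m$params$maph)))
  want <- t(apply(hid_ph, 1, function(v) oracle_tower(m, "DO", v)))
  expect_equal(got$predictions$DO, want, tolerance = 1e-9)

  mg <- tiny_model("gh", width = 3, lookback = 2, stations = 2, seed = 11)
  for (t in mg$config$tasks) {
    mg$params[[paste0("gate_", t)]]$W[] <- 0
    mg$params[[paste0("gate_", t)]]$b[] <- 0
  }
  gotg <- forward_gh(mg, random_inputs(mg, n = 2))
  for (t in mg$config$tasks) {
    expect_true(all(abs(gotg$gate_weights[[t]] - 0.5) < 1e-12))
  }
})

test_that("with identity weights the hard structure reduces to ReLU(x)", {
  cfg <- structure_config("hard", tasks = "pH", hidden_width = 2,
                          tower_depth = c(pH = 3))
  m <- build_model(cfg, 1, 2, seed = 1)
  for (nm in names(m$params)) {
    m$params[[nm]]$W <- diag(2)
    m$params[[nm]]$b <- c(0, 0)
  }
  got <- forward_hard(m, list(pH = c(2, -2)))
  expect_equal(got$predictions$pH[1, ], c(2, 0))
  enc <- encode_indicators(m, list(pH = c(2, -2)))
  expect_equal(enc$pH[1, ], c(2, 0))
})

test_that("zeroing the soft hidden block reduces towers to zero-padded inputs", {
  set.seed(106)
  m <- tiny_model("soft", width = 3, lookback = 2, stations = 2, seed = 12)
  m$params$hid_1$W[] <- 0; m$params$hid_1$b[] <- 0
  m$params$hid_2$W[] <- 0; m$params$hid_2$b[] <- 0
  X <- random_inputs(m, n = 3)
  got <- forward_soft(m, X)
  outs <- encode_indicators(m, X)
  for (t in m$config$tasks) {
    padded <- cbind(outs[[t]], matrix(0, 3, 3))
    expect_equal(got$predictions[[t]], tower_forward(padded, m, t),
                 tolerance = 1e-12)
  }
  expect_equal(m$dims$tower_in, 6L)   # concat(out_i, hidden) width = 2H
  expect_equal(tiny_model("hard", width = 3)$dims$tower_in, 12L)  # 4H concat
})

test_that("permuting stations with permuted weights permutes predictions", {
  set.seed(107)
  L <- 2; S <- 3
  m <- tiny_model("hard", width = 4, lookback = L, stations = S, seed = 13)
  perm <- c(3, 1, 2)
  m2 <- m
  block <- function(s) ((s - 1) * L + 1):(s * L)
  for (t in m$config$tasks) {
    enc <- paste0("enc_", t)
    for (s in 1:S) {
      m2$params[[enc]]$W[, block(s)] <- m$params[[enc]]$W[, block(perm[s])]
    }
    last <- sprintf("tw_%s_%d", t, m$config$tower_depth[[t]])
    m2$params[[last]]$W <- m$params[[last]]$W[perm, ]
    m2$params[[last]]$b <- m$params[[last]]$b[perm]
  }
  X <- random_inputs(m, n = 2)
  Xp <- lapply(X, function(mat) {
    out <- mat
    for (s in 1:S) out[, block(s)] <- mat[, block(perm[s])]
    out
  })
  p1 <- forward_hard(m, X)$predictions
  p2 <- forward_hard(m2, Xp)$predictions
  for (t in m$config$tasks) {
    expect_equal(p2[[t]], p1[[t]][, perm, drop = FALSE], tolerance = 1e-12)
  }
})

test_that("all four sharing structures emit non-negative station vectors", {
  set.seed(108)
  for (s in names(forwarders)) {
    m <- tiny_model(s, width = 3, lookback = 2, stations = 2, seed = 14)
    got <- forwarders[[s]](m, random_inputs(m, n = 6))
    for (t in m$config$tasks) {
      expect_equal(dim(got$predictions[[t]]), c(6L, 2L))
      expect_true(all(got$predictions[[t]] >= 0))
    }
  }
})

test_that("every tower type emits a station-sized output and zero mlp weights give zero", {
  set.seed(109)
  for (tt in c("mlp", "lstm", "gru", "cnn", "attention")) {
    m <- tiny_model("gh", width = 8, lookback = 2, stations = 3,
                    tower_type = tt, seed = 15)
    got <- forward_gh(m, random_inputs(m, n = 4))
    for (t in m$config$tasks) {
      expect_equal(dim(got$predictions[[t]]), c(4L, 3L))
      expect_true(all(is.finite(got$predictions[[t]])))
    }
    v <- rnorm(m$dims$tower_in)
    expect_length(tower_forward(v, m, "pH"), 3L)
  }
  m0 <- tiny_model("gh", width = 8, lookback = 2, stations = 3, seed = 16)
  for (nm in grep("^tw_pH_", names(m0$params), value = TRUE)) {
    m0$params[[nm]]$W[] <- 0
    m0$params[[nm]]$b[] <- 0
  }
  expect_equal(tower_forward(rnorm(m0$dims$tower_in), m0, "pH"), rep(0, 3))
})

test_that("structure and task mismatches raise structured errors", {
  m <- tiny_model("hard", width = 3)
  expect_error(forward_soft(m, random_inputs(m, 1)),
               class = "aquamtl_config_error")
  expect_error(forward_hard(m, list(pH = rnorm(4))),
               class = "aquamtl_task_error")
  expect_error(tower_forward(rnorm(12), m, "turbidity"))
})
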
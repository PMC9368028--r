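test_that("the joint loss sums per-indicator mean squared errors", {
  ind <- c("pH", "DO", "CODMn", "NH3N")
  perfect <- setNames(lapply(1:4, function(i) matrix(i, 2, 3)), ind)
  expect_equal(mtl_loss(perfect, perfect), 0)

  # one sample, one station, unit error in every indicator
  preds <- setNames(lapply(1:4, function(i) matrix(0, 1, 1)), ind)
  targs <- setNames(lapply(1:4, function(i) matrix(1, 1, 1)), ind)
  expect_equal(mtl_loss(preds, targs), 4)

  # two samples whose summed squared errors are 4 and 0 average to 2
  preds2 <- setNames(lapply(1:4, function(i) matrix(c(0, 5), 2, 1)), ind)
  targs2 <- setNames(lapply(1:4, function(i) matrix(c(1, 5), 2, 1)), ind)
  expect_equal(mtl_loss(preds2, targs2), 2)

  expect_error(mtl_loss(list(), list()), class = "aquamtl_empty_error")
  expect_error(mtl_loss(list(pH = matrix(0, 1, 1)), list(pH = matrix(0, 2, 1))),
               class = "aquamtl_dim_error")
})

test_that("the joint loss agrees with a brute-force recomputation on random tensors", {
  set.seed(31)
  for (rep in 1:20) {
    ind <- c("pH", "DO", "CODMn", "NH3N")
    n <- sample(1:6, 1); s <- sample(1:4, 1)
    preds <- setNames(lapply(ind, function(i) matrix(rnorm(n * s), n, s)), ind)
    targs <- setNames(lapply(ind, function(i) matrix(rnorm(n * s), n, s)), ind)
    expect_equal(mtl_loss(preds, targs), oracle_mtl_loss(preds, targs),
                 tolerance = 1e-12)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  p <- generate_panel(synthetic_config(n_stations = 3, n_weeks = 80, seed = 4))
  sp <- scaled_splits(p, lookback = 5)
  run <- function() {
    m <- build_model(structure_config("gh", hidden_width = 6), 5, 3, seed = 8)
    train_model(m, sp$train, sp$val,
                train_config(epochs = 3, batch_size = 8, seed = 8))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
})

test_that("training reduces the loss on a predictable synthetic panel", {
  # low observation noise and strong autocorrelation keep the irreducible
  # loss floor far below the untrained starting loss
  p <- generate_panel(synthetic_config(n_stations = 4, n_weeks = 120,
                                       phi_shared = 0.9, latent_sd = 1,
                                       loadings = 1, mu = 10,
                                       sigma_idio = 0.05, sigma_noise = 0.02,
                                       amplitude = 0.2, seed = 6))
  sp <- scaled_splits(p, lookback = 10)
  m <- build_model(structure_config("gh", hidden_width = 8), 10, 4, seed = 7)
  fit <- train_model(m, sp$train, sp$val,
                     train_config(epochs = 15, batch_size = 8, seed = 7))
  expect_lt(tail(fit$history$train_loss, 1), 0.5 * fit$history$train_loss[1])
  expect_equal(nrow(fit$history), 15)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$train_loss >= 0))
})

test_that("a constant panel is learned to near-zero loss", {
  cfg <- synthetic_config(n_stations = 1, n_weeks = 60, loadings = 0,
                          sigma_idio = 0, sigma_noise = 0, amplitude = 0,
                          seed = 5)
  p <- generate_panel(cfg)
  w <- make_windows(p, 5, 1)
  sp <- chronological_split(w)
  m <- build_model(structure_config("gh", hidden_width = 4), 5, 1, seed = 3)
  m <- init_output_bias(m, sp$train)
  fit <- train_model(m, sp$train, sp$val,
                     train_config(learning_rate = 0.01, epochs = 50,
                                  batch_size = 16, seed = 3))
  best <- min(fit$history$train_loss)
  expect_lt(best, 1e-4)
})

test_that("one epoch with full-batch data takes exactly one optimizer step", {
  p <- generate_panel(synthetic_config(n_stations = 2, n_weeks = 40, seed = 2))
  sp <- scaled_splits(p, lookback = 5)
  m <- build_model(structure_config("hard", hidden_width = 4), 5, 2, seed = 2)
  fit <- train_model(m, sp$train, sp$val,
                     train_config(epochs = 1, batch_size = n_samples(sp$train),
                                  seed = 2))
  expect_equal(fit$steps, 1L)
})

test_that("a non-finite loss aborts with the epoch and batch named", {
  p <- generate_panel(synthetic_config(n_stations = 2, n_weeks = 40, seed = 2))
  sp <- scaled_splits(p, lookback = 5)
  bad <- sp$train
  bad$Y[1, 1, 1] <- Inf
  m <- build_model(structure_config("hard", hidden_width = 4), 5, 2, seed = 2)
  expect_error(train_model(m, bad, sp$val, train_config(epochs = 1, seed = 2)),
               regexp = "epoch 1", class = "aquamtl_numeric_error")
})

test_that("analytic gradients match finite differences for small models", {
  p <- generate_panel(synthetic_config(n_stations = 2, n_weeks = 40, seed = 12))
  sp <- scaled_splits(p, lookback = 2)
  batch <- aquamtl:::subset_windows(sp$train, 1:3)
  for (s in c("hard", "gh")) {
    m <- build_model(structure_config(s, hidden_width = 3), 2, 2, seed = 19)
    gc <- gradient_check(m, batch)
    expect_lt(gc$max_rel_err, 1e-4)
    expect_gte(gc$n_skipped, 0)
    expect_gt(gc$n_checked, 0)
  }
})

test_that("single-task gradients are unaffected by the other tasks", {
  p <- generate_panel(synthetic_config(n_stations = 2, n_weeks = 40, seed = 13))
  sp <- scaled_splits(p, lookback = 2)
  m4 <- build_model(structure_config("single_task", hidden_width = 3), 2, 2,
                    seed = 21)
  m2 <- build_model(structure_config("single_task", hidden_width = 3,
                                     tasks = c("pH", "DO")), 2, 2, seed = 22)
  shared <- intersect(names(m4$params), names(m2$params))
  m2$params[shared] <- m4$params[shared]
  X4 <- aquamtl:::windows_to_inputs(sp$train, m4$config$tasks)
  Y4 <- aquamtl:::windows_to_targets(sp$train, m4$config$tasks)
  g4 <- aquamtl:::loss_and_grads(m4, X4, Y4)$grads
  g2 <- aquamtl:::loss_and_grads(m2, X4[c("pH", "DO")], Y4[c("pH", "DO")])$grads
  for (nm in names(g2)) {
    expect_equal(g2[[nm]], g4[[nm]], tolerance = 1e-12)
  }
})

test_that("the global seed makes initialisation reproducible", {
  set_global_seed(123)
  a <- build_model(structure_config("hard", hidden_width = 3), 2, 2)
  set_global_seed(123)
  b <- build_model(structure_config("hard", hidden_width = 3), 2, 2)
  expect_identical(a$params, b$params)
  set_global_seed(124)
  c <- build_model(structure_config("hard", hidden_width = 3), 2, 2)
  expect_false(identical(a$params, c$params))
})
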
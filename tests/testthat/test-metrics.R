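test_that("rmse, mae and mape reproduce hand-computed examples", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1, 4), 3)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_equal(mae(0, -1), 1)
  expect_equal(mape(c(1, 2), c(1.1, 1.8)), 0.1)
  expect_equal(mape(c(5, 5), c(5, 5)), 0)
})

test_that("metrics agree with brute-force implementations on random vectors", {
  set.seed(41)
  for (rep in 1:1000) {
    n <- sample(1:20, 1)
    y <- rnorm(n, mean = 5)
    yhat <- y + rnorm(n)
    expect_equal(rmse(y, yhat), oracle_rmse(y, yhat), tolerance = 1e-10)
    expect_equal(mae(y, yhat), oracle_mae(y, yhat), tolerance = 1e-10)
    expect_equal(mape(y, yhat), oracle_mape(y, yhat), tolerance = 1e-10)
  }
})

test_that("mape refuses zero targets and names the offending indices", {
  err <- tryCatch(mape(c(1, 0, 2, 0), c(1, 1, 2, 1)), error = identity)
  expect_s3_class(err, "aquamtl_mape_error")
  expect_equal(err$indices, c(2L, 4L))
  expect_error(rmse(numeric(0), numeric(0)), class = "aquamtl_empty_error")
  expect_error(mae(1:3, 1:2), class = "aquamtl_dim_error")
})

test_that("multi-indicator aggregation is the sum of per-indicator values", {
  expect_equal(aggregate_multi(c(0.262, 1.182, 1.515, 0.403)), 3.362)
  expect_equal(aggregate_multi(c(0.181, 0.796, 0.592, 0.154)), 1.723)
  expect_equal(aggregate_multi(c(0, 0, 0, 0)), 0)
  expect_equal(aggregate_multi(c(1, 2, 3, 4), method = "mean"), 2.5)
})

test_that("relative improvement uses the printed-table convention", {
  expect_equal(relative_improvement(0.282, 0.262), 7.1)
  expect_equal(relative_improvement(3.476, 3.362), 3.3)
  expect_equal(relative_improvement(1, 1), 0)
  expect_error(relative_improvement(0, 1), class = "aquamtl_metric_error")
  # half-away-from-zero rounding at the boundary
  expect_equal(relative_improvement(100, 99.85), 0.2)
  expect_equal(relative_improvement(100, 100.15), -0.2)
})

test_that("a perfect predictor evaluates to zero on every metric", {
  # panel rising by exactly 1 per week: the target equals last value + 1,
  # which an affine model reproduces exactly
  p <- ramp_panel(2, 30)
  w <- make_windows(p, 5, 1)
  cfg <- structure_config("linear_baseline")
  m <- build_model(cfg, 5, 2, seed = 1)
  for (t in cfg$tasks) {
    W <- matrix(0, 2, 10)
    W[1, 5] <- 1   # last lookback step of station 1
    W[2, 10] <- 1  # last lookback step of station 2
    m$params[[paste0("lin_", t)]]$W <- W
    m$params[[paste0("lin_", t)]]$b <- c(1, 1)
  }
  rep <- evaluate(m, w, unit_scaler())
  expect_equal(unname(rep$aggregate), c(0, 0, 0))
  expect_equal(rep$n, n_samples(w) * 2)
})

test_that("evaluate matches an external recomputation from dumped predictions", {
  p <- generate_panel(synthetic_config(n_stations = 3, n_weeks = 100, seed = 44))
  sp <- scaled_splits(p, lookback = 5)
  m <- build_model(structure_config("soft", hidden_width = 6), 5, 3, seed = 45)
  fit <- train_model(m, sp$train, sp$val,
                     train_config(epochs = 3, batch_size = 8, seed = 45))
  rep <- evaluate(fit$model, sp$test, sp$scaler)
  preds <- predict(fit$model, sp$test, scaler = sp$scaler)
  truth <- aquamtl:::windows_to_targets(invert_scaler(sp$test, sp$scaler),
                                        m$config$tasks)
  for (t in m$config$tasks) {
    row <- rep$per_indicator[rep$per_indicator$indicator == t, ]
    expect_equal(row$rmse, oracle_rmse(as.vector(truth[[t]]), as.vector(preds[[t]])),
                 tolerance = 1e-10)
    expect_equal(row$mape, oracle_mape(as.vector(truth[[t]]), as.vector(preds[[t]])),
                 tolerance = 1e-10)
  }
  expect_identical(unname(rep$aggregate["rmse"]), sum(rep$per_indicator$rmse))
})
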
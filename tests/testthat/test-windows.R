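test_that("window counts match T - lookback - horizon + 1", {
  expect_equal(n_samples(make_windows(ramp_panel(2, 50), 10, 1)), 40)
  expect_equal(n_samples(make_windows(ramp_panel(2, 10), 10, 1)), 0)
  w1 <- make_windows(ramp_panel(2, 11), 10, 1)
  expect_equal(n_samples(w1), 1)
  expect_equal(w1$target_times, ramp_panel(2, 11)$timestamps[11])
})

test_that("window targets align with the panel by brute-force re-indexing", {
  set.seed(7)
  for (rep in 1:5) {
    nt <- sample(12:30, 1)
    lb <- sample(2:6, 1)
    hz <- sample(1:2, 1)
    v <- array(rnorm(2 * nt * 4), dim = c(2, nt, 4))
    p <- indicator_panel(v, as.Date("2020-01-06") + 7 * (seq_len(nt) - 1))
    w <- make_windows(p, lb, hz)
    expect_equal(n_samples(w), max(0, nt - lb - hz + 1))
    for (k in seq_len(n_samples(w))) {
      for (i in 1:4) {
        expect_equal(w$Y[k, , i], v[, k + lb + hz - 1, i])
        expect_equal(w$X[k, , , i], t(v[, k:(k + lb - 1), i]))
      }
    }
  }
})

test_that("chronological split gives 60/20/20 on n = 100", {
  w100 <- make_windows(ramp_panel(1, 110), 10, 1)
  expect_equal(n_samples(w100), 100)
  sp <- chronological_split(w100)
  expect_equal(sapply(sp, n_samples), c(train = 60, val = 20, test = 20))
})

test_that("split sizes follow floor arithmetic on arbitrary n and n = 0 is empty", {
  for (nt in c(21, 25, 47)) {
    w <- make_windows(ramp_panel(1, nt + 10), 10, 1)
    n <- n_samples(w)
    sp <- chronological_split(w)
    expect_equal(n_samples(sp$train), floor(0.6 * n))
    expect_equal(n_samples(sp$val), floor(0.2 * n))
    expect_equal(n_samples(sp$test), n - floor(0.6 * n) - floor(0.2 * n))
  }
  w0 <- make_windows(ramp_panel(1, 10), 10, 1)
  sp0 <- chronological_split(w0)
  expect_equal(sapply(sp0, n_samples), c(train = 0, val = 0, test = 0))
})

test_that("split is leakage-free and partitions the samples", {
  w <- make_windows(ramp_panel(1, 60), 10, 1)
  sp <- chronological_split(w)
  expect_lt(max(sp$train$target_times), min(sp$val$target_times))
  expect_lt(max(sp$val$target_times), min(sp$test$target_times))
  expect_equal(sort(c(sp$train$target_times, sp$val$target_times, sp$test$target_times)),
               sort(w$target_times))
  expect_error(split_spec(0.5, 0.2, 0.2), class = "aquamtl_split_error")
})

test_that("min-max scaler maps the training range to [0,1] and inverts exactly", {
  p <- ramp_panel(2, 40)
  sp <- chronological_split(make_windows(p, 5, 1))
  sc <- fit_scaler(sp$train)
  tr <- apply_scaler(sp$train, sc)
  expect_gte(min(tr$X), 0)
  expect_lte(max(tr$Y), 1)
  te <- apply_scaler(sp$test, sc)
  back <- invert_scaler(te, sc)
  expect_equal(back$X, sp$test$X, tolerance = 1e-9)
  expect_equal(back$Y, sp$test$Y, tolerance = 1e-9)
  # test-period values beyond the training range extrapolate, unclipped
  expect_gt(max(te$Y), 1)
})

test_that("scaler arithmetic matches the affine formula and refuses constants", {
  sc <- unit_scaler()
  sc$min[] <- 6; sc$max[] <- 9
  expect_equal(aquamtl:::scale_values(7.5, 6, 9), 0.5)
  expect_equal(aquamtl:::scale_values(10, 6, 9), 4 / 3)
  x <- 8.13
  expect_equal(aquamtl:::scale_values(aquamtl:::scale_values(x, 6, 9), 6, 9,
                                      invert = TRUE), x, tolerance = 1e-12)
  v <- array(1, dim = c(1, 30, 4))
  p <- indicator_panel(v, as.Date("2020-01-06") + 7 * 0:29)
  sp <- chronological_split(make_windows(p, 5, 1))
  expect_error(fit_scaler(sp$train), class = "aquamtl_scaler_error")
})
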
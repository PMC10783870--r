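test_that("normalization centers and scales per component", {
  ax <- time_axis(0, 0.01, 2)
  y <- time_series(matrix(c(1, 3), 1), ax, "ch1")
  x <- time_series(matrix(c(0, 2), 1), ax, "x1", kind = "band")
  nrm <- normalize_inputs(y, x, "l2")
  expect_equal(unname(nrm$y$values[1, ]), c(-1, 1)) # population SD
  expect_equal(nrm$scale_info$mu_y[[1]], 2)

  # already-centered unit-SD series is a fixed point
  set.seed(3)
  v <- rnorm(100)
  v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  ts <- time_series(matrix(v, 1), time_axis(0, 0.01, 100), "ch1")
  xs <- time_series(matrix(rnorm(100), 1), ts$axis, "x1", kind = "band")
  nrm2 <- normalize_inputs(ts, xs, "l2")
  expect_equal(unname(nrm2$y$values[1, ]), v, tolerance = 1e-12)

  const <- time_series(matrix(1, 1, 100), ts$axis, "flat", kind = "band")
  expect_error(normalize_inputs(ts, const, "l2"), "flat")
})

test_that("partitions are contiguous, exhaustive and role-disjoint", {
  ax <- time_axis(0, 0.01, 1000)
  p <- make_partitions(ax, 4)
  expect_equal(p$segments$end - p$segments$start + 1L, rep(250L, 4))

  p3 <- make_partitions(ax, 3, test = TRUE)
  test_segs <- vapply(p3$runs, function(r) r$test, 0L)
  expect_setequal(test_segs, 1:3) # each segment is test exactly once
  for (r in p3$runs) {
    all_samples <- sort(c(segment_samples_for_test(p3, r$train),
                          segment_samples_for_test(p3, r$validation),
                          segment_samples_for_test(p3, r$test)))
    expect_equal(all_samples, 1:1000)
  }
  expect_error(make_partitions(ax, 2, test = TRUE), "at least 3")
  expect_error(make_partitions(time_axis(0, 0.01, 30), 4, min_segment = 0.5),
               "shorter")
})

test_that("proportion_explained matches its defining identity", {
  ax <- time_axis(0, 0.01, 4)
  y <- time_series(matrix(c(1, -1, 1, -1), 1), ax, "ch1")
  yhat <- time_series(matrix(c(0.5, -0.5, 0.5, -0.5), 1), ax, "ch1")
  expect_equal(unname(proportion_explained(y, y, "l2")), 1)
  mu <- time_series(matrix(0, 1, 4), ax, "ch1")
  expect_equal(unname(proportion_explained(y, mu, "l2")), 0)
  expect_equal(unname(proportion_explained(y, yhat, "l2")), 0.75)
  flat <- time_series(matrix(2, 1, 4), ax, "ch1")
  expect_error(proportion_explained(flat, yhat, "l2"), "variability")
})

test_that("basis windows are unit-sum and widen kernel updates", {
  B0 <- basis_matrix(10, 0, 0.01)
  expect_equal(B0, diag(10))
  B <- basis_matrix(50, 0.05, 0.01, "hamming")
  # 5-sample Hamming window, unit sum away from the edges
  expect_equal(sum(B[, 25] != 0), 5)
  expect_equal(sum(B[, 25]), 1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:4) / 4)
  expect_equal(B[23:27, 25], w / sum(w), tolerance = 1e-12)
  # edge truncation drops mass
  expect_lt(sum(B[, 1]), 1)
  expect_error(basis_matrix(50, 0.05, 0.01, "gauss"), "unknown")
})

test_that("lag window (0, 0.5) at 100 Hz yields exactly 50 lags", {
  expect_equal(n_lags(0, 0.5, 0.01), 50L)
  expect_equal(n_lags(-0.5, 0, 0.01), 50L)
  d <- small_sim(2, duration = 20, tmax = 0.3)
  fit <- boost_fit(d$response, d$predictors, boost_config(0, 0.5), k = 3)
  expect_equal(fit$kernel$lag_axis$n_samples, 50L)
  expect_error(boost_config(0.5, 0.5), "smaller")
})

test_that("boosting recovers a noiseless kernel and ignores unrelated noise", {
  d <- small_sim(5, duration = 30, snr_db = Inf, tmax = 0.3)
  fit <- boost_fit(d$response, d$predictors, boost_config(0, 0.3), k = 3)
  expect_gte(min(kernel_correlation(fit$kernel, d$truth)), 0.95)

  # null: response independent of the predictor
  x <- pink_noise(2000, 1, seed = 31)
  set.seed(32)
  y <- time_series(rnorm(2000), x$axis, "eeg")
  x <- time_series(x$values, x$axis, "env", kind = "band")
  fit0 <- cross_validate(y, x, boost_config(0, 0.3), k = 5)
  # early stopping keeps most coefficients at exact zero in every run; the
  # run-averaged kernel unions the few chance coordinates of the k runs
  per_run_zero <- vapply(fit0$run_coefs, function(m) mean(m == 0), 0)
  expect_gte(median(per_run_zero), 0.8)
  expect_gte(fit0$kernel$zero_fraction, 0.5)
  expect_lte(max(fit0$proportion_explained), 0.01)
})

test_that("training error is non-increasing and the returned kernel is the validation optimum", {
  d <- small_sim(8, duration = 20, tmax = 0.3)
  fit <- boost_fit(d$response, d$predictors, boost_config(0, 0.3), k = 3)
  h <- fit$history
  for (r in unique(h$run)) {
    tr <- h$training_error[h$run == r]
    expect_true(all(diff(tr) <= 1e-10))
    vals <- h$validation_error[h$run == r]
    # stopping rule: at most 2 consecutive increases at the end
    increases <- diff(vals) > 0
    if (length(increases) >= 2) {
      run_len <- rle(increases)
      expect_lte(max(run_len$lengths[run_len$values]), 2)
    }
  }
})

test_that("cross-validation predicts every sample exactly once and is deterministic", {
  d <- small_sim(9, duration = 20, tmax = 0.3)
  fit1 <- cross_validate(d$response, d$predictors, boost_config(0, 0.3), k = 3)
  fit2 <- cross_validate(d$response, d$predictors, boost_config(0, 0.3), k = 3)
  expect_identical(fit1$kernel$values, fit2$kernel$values)
  expect_identical(fit1$proportion_explained, fit2$proportion_explained)
  expect_true(all(is.finite(fit1$predicted$values))) # every sample predicted
  expect_true(fit1$cross_validated)
  expect_lte(max(fit1$proportion_explained), 1)
})

test_that("original-units kernel reproduces normalized-space predictions", {
  d <- small_sim(12, duration = 20, tmax = 0.3)
  fit <- boost_fit(d$response, d$predictors, boost_config(0, 0.3), k = 3)
  # predict via original-units kernel + intercept
  yhat1 <- predict(fit, d$predictors)
  # predict via normalized quantities, then un-scale
  nrm <- normalize_inputs(d$response, d$predictors, "l2")
  si <- fit$kernel$scale_info
  h_norm <- fit$kernel$values
  for (i in seq_len(dim(h_norm)[1])) {
    for (ch in seq_len(dim(h_norm)[3])) {
      h_norm[i, , ch] <- h_norm[i, , ch] * si$s_x[i] / si$s_y[ch]
    }
  }
  k_norm <- trf_kernel(h_norm, fit$kernel$lag_axis$tstart, fit$kernel$lag_axis$tstep)
  yh_n <- convolve_mtrf(nrm$x, k_norm)$values
  yhat2 <- yh_n * si$s_y + si$mu_y
  expect_lt(max(abs(yhat1$values - yhat2)), 1e-8)
})

test_that("model comparison is exactly zero for identical predictor sets", {
  d <- small_sim(14, duration = 20, tmax = 0.3)
  cmp <- compare_models(d$response, d$predictors, d$predictors,
                        boost_config(0, 0.3), k = 3)
  expect_equal(unname(cmp$delta), rep(0, length(cmp$delta)))
  expect_equal(nrow(cmp$table), n_components(d$response))
})

test_that("backward models use negative lags to reconstruct the stimulus", {
  expect_error(fit_backward(NULL, NULL, boost_config(0, 0.5)), "negative")
  set.seed(41)
  n <- 3000
  ax <- time_axis(0, 0.01, n)
  stim <- pink_noise(n, 1, seed = 42)
  stim <- time_series(stim$values, ax, "envelope", kind = "scalar")
  # response channels = delayed noisy mixtures of the stimulus
  mix <- rbind(c(0.8, 3), c(-0.6, 6)) # weight, delay in samples
  resp <- matrix(0, 2, n)
  for (ch in 1:2) {
    dly <- mix[ch, 2]
    resp[ch, (dly + 1):n] <- mix[ch, 1] * stim$values[1, 1:(n - dly)]
    resp[ch, ] <- resp[ch, ] + rnorm(n, sd = sd(resp[ch, ]))
  }
  response <- time_series(resp, ax, c("ch1", "ch2"))
  dec <- fit_backward(stim, response, boost_config(-0.2, 0),
                      cross_validated = TRUE, k = 3)
  expect_equal(fit_backward_lag_count(dec), 20L)
  r <- stats::cor(dec$predicted$values[1, ], stim$values[1, ])
  expect_gt(r, 0.5)

  # decoding pure noise gives near-zero held-out correlation
  set.seed(43)
  noise_resp <- time_series(matrix(rnorm(2 * n), 2, n), ax, c("ch1", "ch2"))
  dec0 <- fit_backward(stim, noise_resp, boost_config(-0.2, 0),
                       cross_validated = TRUE, k = 3)
  r0 <- stats::cor(dec0$predicted$values[1, ], stim$values[1, ])
  expect_lt(abs(r0), 0.05)
})

test_that("selective stopping freezes predictors instead of halting the run", {
  d <- small_sim(17, duration = 30, n_bands = 2, tmax = 0.3)
  fit <- boost_fit(d$response, d$predictors,
                   boost_config(0, 0.3, selective_stopping = 2), k = 3)
  expect_gte(min(kernel_correlation(fit$kernel, d$truth)), 0.5)
  # both generating predictors received steps before freezing
  expect_setequal(unique(fit$history$predictor), d$predictors$labels)
})

test_that("ridge recovers noiselessly at lambda 0 and shrinks to zero at large lambda", {
  d <- small_sim(19, duration = 30, snr_db = Inf, tmax = 0.3)
  rk <- ridge_mtrf(d$response, d$predictors, 0, 0.3, lambda = 0,
                   scale_data = FALSE)
  expect_lt(max(abs(rk$values - d$truth$values)), 1e-6)

  big <- ridge_mtrf(d$response, d$predictors, 0, 0.3, lambda = 1e12)
  expect_lt(max(abs(big$values)), 1e-6)

  # collinear predictors at lambda 0 are singular, with guidance
  x2 <- d$predictors$values
  x2 <- rbind(x2, x2[1, ])
  dup <- time_series(x2, d$predictors$axis, c("b1", "b2", "b1copy"), "band")
  expect_error(ridge_mtrf(d$response, dup, 0, 0.3, lambda = 0), "lambda > 0")
})
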
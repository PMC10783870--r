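test_that("time axes report alignment and timestamps correctly", {
  ax <- time_axis(0.5, 0.01, 100)
  expect_equal(axis_times(ax)[1], 0.5)
  expect_equal(axis_times(ax)[100], 0.5 + 99 * 0.01)
  expect_true(axes_aligned(ax, time_axis(0.5 + 1e-12, 0.01, 100)))
  expect_false(axes_aligned(ax, time_axis(0.5, 0.01, 99)))
  expect_error(time_axis(0, -0.01, 10), "positive")
  expect_error(time_axis(0, 0.01, 0), "at least 1")
})

test_that("time series construction enforces its invariants", {
  ax <- time_axis(0, 0.01, 10)
  expect_error(time_series(matrix(1, 2, 9), ax), "samples")
  expect_error(time_series(matrix(c(1, NA), 1, 2), time_axis(0, 1, 2)), "finite")
  expect_error(time_series(matrix(1, 2, 10), ax, labels = c("a", "a")), "unique")
  ts <- time_series(1:10, ax)
  expect_equal(n_components(ts), 1L)
  expect_equal(sampling_rate(ts), 100)
})

test_that("resampling preserves DC and reproduces band-limited sinusoids", {
  dc <- ts_resample(time_series(rep(3, 500), time_axis(0, 1 / 500, 500)), 100)
  expect_equal(unname(dc$values[1, ]), rep(3, 100), tolerance = 1e-12)
  expect_equal(dc$axis$tstep, 0.01)

  t <- (0:9999) / 1000
  ts <- time_series(sin(2 * pi * 5 * t), time_axis(0, 1e-3, 10000))
  r <- ts_resample(ts, 100)
  expect_equal(r$axis$tstep, 0.01)
  ref <- sin(2 * pi * 5 * axis_times(r$axis))
  interior <- 50:(r$axis$n_samples - 50)
  expect_lt(max(abs(r$values[1, interior] - ref[interior])), 0.01)

  expect_error(ts_resample(r, 500), "upsampling")
  expect_error(ts_resample(r, -1), "positive")
})

test_that("band-pass filtering is zero-phase with the specified selectivity", {
  fs <- 200
  n <- 4000
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 1 * tt) + sin(2 * pi * 10 * tt) + sin(2 * pi * 40 * tt)
  out <- ts_bandpass(time_series(x, time_axis(0, 1 / fs, n)), 0.5, 20)
  amp <- function(sig, f) 2 * abs(stats::fft(sig)[f * n / fs + 1]) / n
  expect_gt(amp(out$values[1, ], 10), 0.9)   # passband within 10%
  expect_lt(amp(out$values[1, ], 40), 0.1)   # stopband below 10%

  zero <- ts_bandpass(time_series(numeric(n), time_axis(0, 1 / fs, n)), 0.5, 20)
  expect_equal(max(abs(zero$values)), 0)

  imp <- numeric(2001)
  imp[1001] <- 1
  ir <- ts_bandpass(time_series(imp, time_axis(0, 1 / fs, 2001)), 0.5, 20)
  v <- ir$values[1, ]
  expect_lt(max(abs(v[1001 + 1:500] - v[1001 - 1:500])), 1e-12)

  expect_error(ts_bandpass(out, 10, 150), "Nyquist")
})

test_that("convolve_mtrf matches the brute-force double sum", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    k <- trf_kernel(inst$h, tmin = inst$lag0 * inst$tstep, tstep = inst$tstep)
    ts <- time_series(inst$x, time_axis(0, inst$tstep, inst$n), kind = "band")
    got <- convolve_mtrf(ts, k)$values
    ref <- brute_convolve(inst$x, inst$h, inst$lag0)
    expect_lt(max(abs(got - ref)), 1e-10)
  }
})

test_that("convolution annihilator, identity and linearity hold", {
  set.seed(4)
  x <- matrix(rnorm(100), 1, 100)
  ts <- time_series(x, time_axis(0, 0.01, 100), kind = "band")
  zero_k <- trf_kernel(array(0, c(1, 5, 1)), 0, 0.01)
  expect_equal(max(abs(convolve_mtrf(ts, zero_k)$values)), 0)

  ident <- trf_kernel(array(c(1, 0, 0), c(1, 3, 1)), 0, 0.01)
  expect_equal(unname(convolve_mtrf(ts, ident)$values), unname(x), tolerance = 1e-12)

  h1 <- array(rnorm(10), c(1, 10, 1))
  h2 <- array(rnorm(10), c(1, 10, 1))
  a <- 2.5
  b <- -1.3
  combo <- trf_kernel(a * h1 + b * h2, 0, 0.01)
  lhs <- convolve_mtrf(ts, combo)$values
  rhs <- a * convolve_mtrf(ts, trf_kernel(h1, 0, 0.01))$values +
    b * convolve_mtrf(ts, trf_kernel(h2, 0, 0.01))$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  expect_error(convolve_mtrf(time_series(matrix(0, 2, 100), ts$axis), ident),
               "component")
})

test_that("epoch averaging recovers event-locked segments", {
  ax <- time_axis(0, 0.01, 300)
  base <- matrix(0, 1, 300)
  shape <- sin(seq(0, pi, length.out = 20))
  resp <- base
  resp[1, 51:70] <- shape
  ts <- time_series(resp, ax, "ch1")
  avg <- epoch_average(ts, event_table(0.5), 0, 0.2)
  expect_equal(unname(avg[1, ]), shape, tolerance = 1e-12)
  expect_equal(attr(avg, "n_dropped"), 0L)

  # +1 and -1 windows cancel
  resp2 <- base
  resp2[1, 51:70] <- 1
  resp2[1, 151:170] <- -1
  avg2 <- epoch_average(time_series(resp2, ax, "ch1"),
                        event_table(c(0.5, 1.5)), 0, 0.2)
  expect_equal(max(abs(avg2)), 0)

  # impulse-train response with a known evoked shape, no overlap
  onsets <- c(0.3, 1.0, 1.9)
  resp3 <- base
  for (on in onsets) resp3[1, (on * 100 + 1):(on * 100 + 20)] <- shape
  avg3 <- epoch_average(time_series(resp3, ax, "ch1"), event_table(onsets), 0, 0.2)
  expect_equal(unname(avg3[1, ]), shape, tolerance = 1e-12)

  # events with incomplete windows are dropped and counted
  avg4 <- epoch_average(ts, event_table(c(0.5, 2.95)), 0, 0.2)
  expect_equal(attr(avg4, "n_dropped"), 1L)
  expect_error(epoch_average(ts, event_table(2.99), 0, 0.2), "no event")
})

test_that("rereferencing subtracts the designated channel mean", {
  ts <- time_series(rbind(1:5, rep(2, 5), rep(4, 5)), time_axis(0, 0.1, 5),
                    c("a", "m1", "m2"))
  out <- rereference(ts, c("m1", "m2"))
  expect_equal(unname(out$values["a", ]), (1:5) - 3)
  expect_error(rereference(ts, "nope"), "unknown")
})
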
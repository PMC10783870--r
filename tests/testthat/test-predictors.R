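test_that("gammatone spectrogram localizes a pure tone and rejects bad input", {
  fs <- 11025
  tw <- (0:(fs * 0.5 - 1)) / fs
  tone <- time_series(sin(2 * pi * 1000 * tw), time_axis(0, 1 / fs, length(tw)))
  sg <- gammatone_spectrogram(tone, n_filters = 64, fmin = 100, fmax = 4000,
                              frame_rate = 100)
  m <- rowMeans(sg$values[, 10:45]) # steady-state frames
  pk <- unname(which.max(m))
  expect_equal(pk, which.min(abs(sg$band_centers - 1000)))
  # monotone decay away from the tone (tiny numeric ripple tolerated)
  expect_lt(max(diff(m[pk:length(m)])), 0.01 * max(m))
  expect_lt(max(diff(rev(m[1:pk]))), 0.01 * max(m))
  expect_true(all(sg$values >= 0))

  silence <- time_series(numeric(4000), time_axis(0, 1 / fs, 4000))
  expect_equal(max(gammatone_spectrogram(silence, 16, 100, 4000, 100)$values), 0)

  stereo <- time_series(matrix(0, 2, 100), time_axis(0, 1 / fs, 100))
  expect_error(gammatone_spectrogram(stereo), "mono")
  expect_error(gammatone_spectrogram(tone, fmax = fs), "Nyquist")
})

test_that("band binning conserves per-sample total power", {
  set.seed(11)
  sg <- spectrogram(matrix(abs(rnorm(256 * 40)), 256, 40),
                    time_axis(0, 0.01, 40), sort(runif(256, 50, 5000)))
  b8 <- bin_bands(sg, 8)
  expect_equal(n_components(b8), 8L)
  expect_lt(max(abs(colSums(b8$values) - colSums(sg$values))), 1e-10)
  expect_identical(bin_bands(sg, 256), sg)
  expect_error(bin_bands(sg, 0), "at least 1")

  u <- spectrogram(matrix(1, 4, 5), time_axis(0, 0.01, 5), c(1, 2, 4, 8))
  b2 <- bin_bands(u, 2)
  expect_equal(unname(b2$values), matrix(2, 2, 5))
  expect_equal(b2$band_centers, c(sqrt(2), sqrt(32)))
})

test_that("envelope equals the one-bin reduction", {
  sg <- spectrogram(rbind(c(1, 3), c(2, 4)), time_axis(0, 0.01, 2), c(100, 200))
  env <- sgram_envelope(sg)
  expect_equal(unname(env$values[1, ]), c(3, 7))
  expect_equal(unname(env$values[1, ]), unname(bin_bands(sg, 1)$values[1, ]))
  one <- spectrogram(matrix(1:5, 1), time_axis(0, 0.01, 5), 100)
  expect_equal(unname(sgram_envelope(one)$values), unname(one$values))
})

test_that("response-scale transforms have the specified endpoints", {
  sg <- spectrogram(matrix(c(0, 1, 4, 16), 1), time_axis(0, 0.01, 4), 100)
  expect_equal(apply_scale(sg, "linear")$values, sg$values)
  expect_equal(unname(apply_scale(sg, "power", exponent = 1)$values),
               unname(sg$values))
  expect_equal(unname(apply_scale(sg, "power", exponent = 0.5)$values[1, 3]), 2)

  lg <- apply_scale(sg, "log", floor_db = -50)
  expect_equal(unname(lg$values[1, 4]), 50) # ref -> -floor_db
  expect_equal(unname(lg$values[1, 1]), 0)  # zero -> floor -> 0
  expect_true(all(is.finite(lg$values)))
  # monotone
  expect_true(all(diff(lg$values[1, ]) >= 0))

  neg <- spectrogram(matrix(1, 1, 2), time_axis(0, 0.01, 2), 100)
  neg$values[1, 1] <- -1
  expect_error(apply_scale(neg, "log"), "non-negative")
})

test_that("onset detection marks rising edges only", {
  ax <- time_axis(0, 0.01, 200)
  for (method in c("rectified_difference", "delayed_inhibition")) {
    const <- onset_spectrogram(spectrogram(matrix(5, 1, 200), ax, 100),
                               method, delay_span = 0.03)
    expect_equal(max(const$values[1, 10:200]), 0)

    stepv <- c(rep(0, 100), rep(1, 100))
    on <- onset_spectrogram(spectrogram(matrix(stepv, 1), ax, 100), method, 0.03)
    active <- which(on$values[1, ] > 0)
    expect_equal(min(active), 101)
    expect_lte(max(active), 101 + 3) # single contiguous burst within the span
    expect_true(all(on$values >= 0))
  }

  # sharp step produces a larger peak than a slow ramp of equal rise
  ramp <- c(rep(0, 80), seq(0, 1, length.out = 40), rep(1, 80))
  stepv <- c(rep(0, 100), rep(1, 100))
  p_ramp <- max(onset_spectrogram(spectrogram(matrix(ramp, 1), ax, 100),
                                  "rectified_difference", 0.03)$values)
  p_step <- max(onset_spectrogram(spectrogram(matrix(stepv, 1), ax, 100),
                                  "rectified_difference", 0.03)$values)
  expect_gt(p_step, p_ramp)

  short_ax <- time_axis(0, 0.01, 10)
  expect_error(onset_spectrogram(spectrogram(matrix(1, 1, 10), short_ax, 100),
                                 delay_span = 0.001), "one sample")

  # non-negativity on random inputs, both methods
  set.seed(21)
  rsg <- spectrogram(matrix(abs(rnorm(3 * 150)), 3, 150), time_axis(0, 0.01, 150),
                     c(100, 200, 400))
  for (method in c("rectified_difference", "delayed_inhibition")) {
    expect_true(all(onset_spectrogram(rsg, method, 0.05)$values >= 0))
  }
})

test_that("impulse predictors place event magnitudes at nearest samples", {
  ax <- time_axis(0, 0.01, 100)
  expect_equal(max(abs(impulse_predictor(event_table(), ax)$values)), 0)

  ev <- event_table(c(0.10, 0.25), value = c(2, 3))
  imp <- impulse_predictor(ev, ax, use_values = TRUE)
  expect_equal(unname(imp$values[1, 11]), 2)
  expect_equal(unname(imp$values[1, 26]), 3)
  expect_equal(sum(imp$values), 5)

  const <- impulse_predictor(ev, ax, use_values = FALSE)
  expect_equal(sum(const$values), 2) # number of in-range events

  out_of_range <- impulse_predictor(event_table(c(0.1, 5)), ax)
  expect_equal(attr(out_of_range, "n_dropped"), 1L)

  # convolving an impulse predictor reproduces direct kernel placement
  h <- array(sin(seq(0, pi, length.out = 10)), c(1, 10, 1))
  k <- trf_kernel(h, 0, 0.01)
  ev2 <- event_table(c(0.2, 0.6), value = c(1.5, -2))
  pred <- impulse_predictor(ev2, ax, use_values = TRUE)
  got <- convolve_mtrf(pred, k)$values[1, ]
  ref <- numeric(100)
  ref[21:30] <- ref[21:30] + 1.5 * h[1, , 1]
  ref[61:70] <- ref[61:70] - 2 * h[1, , 1]
  expect_lt(max(abs(got - ref)), 1e-10)
})

test_that("step predictors hold magnitudes over event durations", {
  ax <- time_axis(0, 0.01, 100)
  ev <- event_table(0.1, value = 1)
  st <- step_predictor(ev, offsets = 0.3, ax)
  expect_equal(sum(st$values > 0), 20)
  expect_equal(sum(st$values), 1 * 0.2 / 0.01)

  zero_dur <- step_predictor(event_table(0.5), offsets = 0.5, ax)
  expect_equal(max(abs(zero_dur$values)), 0)

  expect_error(step_predictor(event_table(0.5), offsets = 0.4, ax), "offset")
})
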
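test_that("pink noise has the right spectrum, mean and variance", {
  x1 <- pink_noise(1000, 2, seed = 5)
  x2 <- pink_noise(1000, 2, seed = 5)
  expect_identical(x1$values, x2$values) # pure function of the seed
  expect_lt(max(abs(rowMeans(x1$values))), 1e-12)
  expect_equal(unname(apply(x1$values, 1, function(v) mean(v^2))), c(1, 1),
               tolerance = 1e-12)
  expect_error(pink_noise(8), "at least 16")

  slopes <- vapply(1:20, function(s) {
    v <- pink_noise(3000, 1, seed = s, rate = 100)$values[1, ]
    sp <- stats::spec.pgram(stats::ts(v, frequency = 100), plot = FALSE,
                            taper = 0, detrend = FALSE)
    ok <- sp$freq >= 1 & sp$freq <= 12.5
    unname(stats::coef(stats::lm(log(sp$spec[ok]) ~ log(sp$freq[ok])))[2])
  }, 0)
  expect_lt(abs(mean(slopes) + 1), 0.15)
})

test_that("ground-truth kernels have the specified structure", {
  k <- ground_truth_kernel("alternating_bands", n_bands = 8, n_channels = 3)
  active <- which(apply(k$values, 1, function(m) any(m != 0)))
  expect_equal(length(active), 2)
  expect_equal(diff(active), 1) # adjacent bands
  # opposite signs: anti-correlated lag profiles
  for (ch in 1:3) {
    expect_lte(stats::cor(k$values[active[1], , ch], k$values[active[2], , ch]), 0)
  }
  # spatial alternation across channels
  expect_equal(k$values[active[1], , 2], -k$values[active[1], , 1])

  z <- ground_truth_kernel("alternating_bands", amplitude = 0)
  expect_equal(max(abs(z$values)), 0)

  g <- ground_truth_kernel("damped_oscillation", n_bands = 2, n_channels = 1)
  expect_true(all(apply(g$values, 1, function(m) any(m != 0))))
  expect_error(ground_truth_kernel("custom"), "values")
})

test_that("simulated datasets respect the convolution model and SNR", {
  spec0 <- sim_spec(duration = 30, rate = 100,
                    truth = ground_truth_kernel(n_bands = 2, n_channels = 1,
                                                tmax = 0.3),
                    snr_db = Inf, seed = 2)
  d0 <- simulate_dataset(spec0)
  ref <- convolve_mtrf(d0$predictors, d0$truth)
  expect_equal(d0$response$values, ref$values, tolerance = 1e-12)

  spec1 <- sim_spec(duration = 60, rate = 100,
                    truth = ground_truth_kernel(n_bands = 2, n_channels = 1,
                                                tmax = 0.3),
                    snr_db = 0, seed = 3)
  d1 <- simulate_dataset(spec1)
  noise <- d1$response$values - d1$signal$values
  sig_p <- mean((d1$signal$values[1, ] - mean(d1$signal$values[1, ]))^2)
  noi_p <- mean((noise[1, ] - mean(noise[1, ]))^2)
  expect_equal(sig_p / noi_p, 1, tolerance = 0.01)

  expect_error(sim_spec(duration = 60, rate = 100,
                        truth = ground_truth_kernel(amplitude = 0),
                        snr_db = 0),
               "all-zero")
  expect_error(sim_spec(duration = 1, rate = 100,
                        truth = ground_truth_kernel()),
               "too short")
})

test_that("requested band correlation is realized empirically", {
  spec <- sim_spec(duration = 60, rate = 100,
                   truth = ground_truth_kernel(n_bands = 8, n_channels = 1),
                   band_correlation = 0.8, snr_db = 0, seed = 11)
  d <- simulate_dataset(spec)
  cors <- vapply(1:7, function(i) {
    stats::cor(d$predictors$values[i, ], d$predictors$values[i + 1, ])
  }, 0)
  expect_lt(max(abs(cors - 0.8)), 0.05 + 0.02) # sampling noise margin at 60 s
})

test_that("event-design simulations place log-normal impulses", {
  spec <- sim_spec(duration = 60, rate = 100,
                   truth = ground_truth_kernel(n_bands = 1, n_channels = 1,
                                               tmax = 0.3),
                   design = "events", event_rate = 3, snr_db = 0, seed = 4)
  d <- simulate_dataset(spec)
  nz <- d$predictors$values[1, ][d$predictors$values[1, ] != 0]
  expect_gt(length(nz), 100) # ~3 events/s over 60 s
  expect_true(all(nz > 0))
})

test_that("groups share a kernel up to the requested between-subject spread", {
  spec <- sim_spec(duration = 20, rate = 100,
                   truth = ground_truth_kernel(n_bands = 2, n_channels = 1,
                                               tmax = 0.3),
                   snr_db = 0, seed = 9)
  g0 <- simulate_group(3, spec, between_subject_sd = 0)
  expect_identical(g0[[1]]$truth$values, g0[[2]]$truth$values)
  g0b <- simulate_group(3, spec, between_subject_sd = 0)
  expect_identical(g0b[[2]]$response$values, g0[[2]]$response$values)

  g1 <- simulate_group(3, spec, between_subject_sd = 0.3)
  expect_false(identical(g1[[1]]$truth$values, g1[[2]]$truth$values))
  expect_error(simulate_group(1, spec), "at least 2")
  expect_error(simulate_group(3, spec, -1), ">= 0")
})
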
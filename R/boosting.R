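#' Boosting configuration
#'
#' Collects the meta-parameters of the boosting estimator. The lag window
#' `[tmin, tmax)` is half-open and sampled at the response rate. `delta` is
#' the coordinate step size in normalized units; when no candidate step
#' reduces the training error, `delta` is halved until it falls below
#' `mindelta`, at which point the run stops. Training also stops after two
#' consecutive validation-error increases (or, with
#' `selective_stopping = s > 0`, a predictor whose accepted steps raise the
#' validation error `s` times is frozen and training continues until all
#' predictors are frozen).
#'
#' @param tmin,tmax Lag window edges in seconds, `tmin < tmax`. Negative lags
#'   give backward (decoding) models.
#' @param delta Initial step size in normalized units.
#' @param mindelta Smallest permitted step; default `delta / 8`.
#' @param error Error norm, `"l2"` (sum of squares) or `"l1"` (sum of
#'   absolute values; more robust to outlier samples).
#' @param basis Width of the smooth basis window in seconds; 0 uses the
#'   impulse basis (each step touches a single lag).
#' @param basis_window Window family: `"hamming"`, `"hann"` or `"boxcar"`.
#' @param selective_stopping Per-predictor freeze count; 0 disables.
#' @param scale_data Center and scale responses and predictors before
#'   fitting (see [normalize_inputs()]).
#' @param max_iter Safety cap on accepted steps per run and channel.
#' @param exclude_onset Exclude the first `tmax - tmin` seconds from
#'   predictive-power evaluation (where the zero-padded convolution is
#'   incomplete); off by default.
#' @param seed Recorded in the result for provenance; the estimator itself is
#'   deterministic.
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(tmin, tmax, delta = 0.005, mindelta = delta / 8,
                         error = c("l2", "l1"), basis = 0,
                         basis_window = "hamming", selective_stopping = 0L,
                         scale_data = TRUE, max_iter = 20000L,
                         exclude_onset = FALSE, seed = NULL) {
  error <- match.arg(error)
  if (tmin >= tmax) stop("`tmin` must be smaller than `tmax`", call. = FALSE)
  if (!(mindelta > 0 && mindelta <= delta)) {
    stop("need 0 < mindelta <= delta", call. = FALSE)
  }
  if (selective_stopping < 0) stop("`selective_stopping` must be >= 0", call. = FALSE)
  if (basis < 0) stop("`basis` must be >= 0", call. = FALSE)
  structure(
    list(tmin = tmin, tmax = tmax, delta = delta, mindelta = mindelta,
         error = error, basis = basis, basis_window = basis_window,
         selective_stopping = as.integer(selective_stopping),
         scale_data = isTRUE(scale_data), max_iter = as.integer(max_iter),
         exclude_onset = isTRUE(exclude_onset), seed = seed),
    class = "boost_config"
  )
}

#' Center and scale responses and predictors
#'
#' Each response channel and each predictor component is independently
#' centered to mean 0 and divided by its scale: the population standard
#' deviation for the l2 error norm, or the mean absolute deviation for l1.
#' Centering eliminates the intercept, which matters because a sparse
#' estimator would otherwise spend coefficients reproducing the mean; scaling
#' puts all predictors on an equal footing so `delta` means the same for each.
#'
#' The returned `scale_info` supports expressing kernels in original units:
#' `h_orig = h_norm * scale_y / scale_x`.
#'
#' @param y Response [time_series()].
#' @param xs Predictor `time_series` (or list; stacked internally).
#' @param error `"l2"` or `"l1"`.
#' @return A list with elements `y`, `x` (normalized series) and `scale_info`
#'   (list with `mu_y`, `s_y`, `mu_x`, `s_x`).
#' @export
normalize_inputs <- function(y, xs, error = c("l2", "l1")) {
  error <- match.arg(error)
  x <- stack_predictors(xs)
  stop_if_not_aligned(y$axis, x$axis, "response and predictors")
  scale_fun <- function(v) {
    if (error == "l2") sqrt(mean((v - mean(v))^2)) else mean(abs(v - mean(v)))
  }
  norm_mat <- function(m, labels, what) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, scale_fun)
    bad <- s == 0 | !is.finite(s)
    if (any(bad)) {
      stop(sprintf("zero-variance %s component(s): %s", what,
                   paste(labels[bad], collapse = ", ")), call. = FALSE)
    }
    list(values = (m - mu) / s, mu = mu, s = s)
  }
  ny <- norm_mat(y$values, y$labels, "response")
  nx <- norm_mat(x$values, x$labels, "predictor")
  list(
    y = with_values(y, ny$values),
    x = with_values(x, nx$values),
    scale_info = list(mu_y = ny$mu, s_y = ny$s, mu_x = nx$mu, s_x = nx$s,
                      error = error)
  )
}

#' k-fold partitioning of a time axis
#'
#' Divides the samples into `k` contiguous, (near-)equal-length segments and
#' assigns segment roles per run. With `test = TRUE` (cross-validation), run
#' `j` uses segment `j` as test set, the next segment (cyclically) as
#' validation set and the rest for training, so every segment is test exactly
#' once. With `test = FALSE` only the validation role rotates.
#'
#' @param axis A [time_axis()].
#' @param k Fold count; at least 3 with `test = TRUE`, else at least 2.
#' @param test Reserve a held-out test segment per run.
#' @param min_segment Minimum admissible segment duration in seconds
#'   (typically the lag-window length); segments shorter than this are an
#'   error.
#' @return An object of class `partition_spec`.
#' @export
make_partitions <- function(axis, k, test = FALSE, min_segment = 0) {
  k <- as.integer(k)
  if (test && k < 3L) stop("`k` must be at least 3 when `test` is enabled", call. = FALSE)
  if (!test && k < 2L) stop("`k` must be at least 2", call. = FALSE)
  n <- axis$n_samples
  bounds <- floor(n * (0:k) / k)
  starts <- bounds[-(k + 1L)] + 1L
  ends <- bounds[-1L]
  if (any((ends - starts + 1L) * axis$tstep < min_segment - 1e-9)) {
    stop("segments are shorter than the lag window; use fewer folds or more data",
         call. = FALSE)
  }
  segments <- tibble::tibble(segment = seq_len(k), start = starts, end = ends)
  runs <- lapply(seq_len(k), function(j) {
    if (test) {
      test_seg <- j
      val_seg <- j %% k + 1L
    } else {
      test_seg <- integer()
      val_seg <- j
    }
    train_seg <- setdiff(seq_len(k), c(test_seg, val_seg))
    list(test = test_seg, validation = val_seg, train = train_seg)
  })
  structure(list(k = k, test = test, segments = segments, runs = runs,
                 n_samples = n),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("<partition_spec> k = %d, %s, %d samples\n", x$k,
              if (x$test) "train/validation/test" else "train/validation",
              x$n_samples))
  invisible(x)
}

segment_samples <- function(partitions, segs) {
  if (!length(segs)) return(integer())
  unlist(lapply(segs, function(s) {
    seq.int(partitions$segments$start[s], partitions$segments$end[s])
  }), use.names = FALSE)
}

#' Smooth basis for TRF construction
#'
#' With a basis, each boosting step adds a scaled copy of a smooth unit-sum
#' window centered at the chosen lag instead of a single impulse, yielding
#' smoother kernels. The returned matrix `B` (lags x lags) maps coefficient
#' space to kernel space: `h = B %*% coefficients`. Windows are normalized to
#' unit sum before truncation at the kernel edges, so `delta` keeps its
#' meaning of total added mass per step.
#'
#' @param n_lags Number of lag bins.
#' @param basis Window width in seconds (0 returns the identity).
#' @param tstep Lag sampling interval in seconds.
#' @param window Window family: `"hamming"`, `"hann"` or `"boxcar"`.
#' @return An `n_lags` x `n_lags` matrix.
#' @export
basis_matrix <- function(n_lags, basis, tstep, window = "hamming") {
  if (basis == 0) return(diag(n_lags))
  w_len <- max(1L, as.integer(round(basis / tstep)))
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(w_len) - 1L) / (w_len - 1L)),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(w_len) - 1L) / (w_len - 1L)),
    boxcar = rep(1, w_len),
    stop("unknown basis window family: ", window, call. = FALSE))
  if (w_len == 1L) w <- 1
  w <- w / sum(w)
  center <- as.integer(ceiling(w_len / 2))
  B <- matrix(0, n_lags, n_lags)
  for (c0 in seq_len(n_lags)) {
    pos <- c0 + seq_len(w_len) - center
    ok <- pos >= 1L & pos <= n_lags
    B[pos[ok], c0] <- w[ok]
  }
  B
}

# Lagged (and optionally basis-smeared) design matrix: column (i - 1) * L + l
# holds predictor i delayed by the l-th lag, zero-padded outside the record.
build_design <- function(x_values, lag_samples, B = NULL) {
  n <- ncol(x_values)
  p <- nrow(x_values)
  L <- length(lag_samples)
  Z <- matrix(0, n, p * L)
  for (i in seq_len(p)) {
    xi <- x_values[i, ]
    Zi <- matrix(0, n, L)
    for (l in seq_len(L)) {
      lag <- lag_samples[l]
      if (lag >= 0) {
        if (lag < n) Zi[(lag + 1L):n, l] <- xi[1L:(n - lag)]
      } else {
        if (-lag < n) Zi[1L:(n + lag), l] <- xi[(1L - lag):n]
      }
    }
    if (!is.null(B)) Zi <- Zi %*% B
    Z[, ((i - 1L) * L + 1L):(i * L)] <- Zi
  }
  Z
}

resolve_lags <- function(config, tstep) {
  L <- n_lags(config$tmin, config$tmax, tstep)
  if (L < 1L) stop("lag window contains zero lags", call. = FALSE)
  as.integer(round(config$tmin / tstep)) + seq_len(L) - 1L
}

# run the C++ core for one run; returns J x C coefficient matrix + histories
run_boost <- function(Z, Yn, partitions, run, config, comp_of_col) {
  train_idx <- segment_samples(partitions, run$train)
  val_idx <- segment_samples(partitions, run$validation)
  res <- boost_run_cpp(Z, Yn, train_idx - 1L, val_idx - 1L,
                       config$delta, config$mindelta,
                       if (config$error == "l2") 2L else 1L,
                       config$selective_stopping, comp_of_col,
                       config$max_iter)
  res
}

coefs_to_kernel_values <- function(coefs, p, L, B = NULL) {
  # coefs: (p*L) x C -> array (p, L, C), through the basis if present
  C <- ncol(coefs)
  out <- array(0, c(p, L, C))
  for (ch in seq_len(C)) {
    m <- matrix(coefs[, ch], nrow = L) # lags x p (column i = predictor i)
    if (!is.null(B)) m <- B %*% m
    out[, , ch] <- t(m)
  }
  out
}

history_tibble <- function(histories_by_run, channel_labels, predictor_labels, L,
                           lag_samples, tstep) {
  rows <- list()
  for (run_i in seq_along(histories_by_run)) {
    hl <- histories_by_run[[run_i]]
    for (ch in seq_along(hl)) {
      H <- hl[[ch]]
      if (!nrow(H)) next
      col <- as.integer(H[, 2L])
      pred_i <- (col - 1L) %/% L + 1L
      lag_i <- (col - 1L) %% L + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        run = run_i, channel = channel_labels[ch], step = as.integer(H[, 1L]),
        predictor = predictor_labels[pred_i],
        lag = lag_samples[lag_i] * tstep,
        direction = H[, 3L], training_error = H[, 4L],
        validation_error = H[, 5L])
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(run = integer(), channel = character(),
                          step = integer(), predictor = character(),
                          lag = numeric(), direction = numeric(),
                          training_error = numeric(),
                          validation_error = numeric()))
  }
  do.call(rbind, rows)
}

#' Fit an mTRF by boosting
#'
#' The core estimator: starting from an all-zero kernel, each iteration
#' evaluates every (predictor, lag) coordinate in both directions and accepts
#' the `delta`-step with the lowest training error; when no step reduces the
#' training error, `delta` is halved until it underflows `mindelta`. After
#' each accepted step the validation error is consulted; two consecutive
#' increases stop the run (early stopping), and the kernel with the smallest
#' validation error in the history is returned. Channels are fitted
#' independently (mass-univariate). The final kernel is the average of the
#' per-run kernels, expressed in original units.
#'
#' @param y Response [time_series()] (channels x time).
#' @param xs Predictor `time_series` or list of aligned ones.
#' @param config A [boost_config()].
#' @param partitions A [partition_spec()]; default `make_partitions(k = 10)`
#'   without a test set. Pass a spec with `test = TRUE` for held-out metrics
#'   (or use [cross_validate()]).
#' @param k Fold count used when `partitions` is not supplied.
#' @return An object of class `trf_fit` with elements `kernel`
#'   ([trf_kernel()], original units), `proportion_explained` and
#'   `residual_error` (per channel; on held-out data iff the partitions have
#'   a test set, see `cross_validated`), `history` (tibble), `config`,
#'   `partitions`, and per-run normalized kernels in `run_kernels`.
#' @seealso [cross_validate()], [ridge_mtrf()], [fit_backward()]
#' @export
boost_fit <- function(y, xs, config, partitions = NULL, k = 10L) {
  stopifnot(inherits(y, "time_series"), inherits(config, "boost_config"))
  tstep <- y$axis$tstep
  lag_samples <- resolve_lags(config, tstep)
  L <- length(lag_samples)
  if (is.null(partitions)) {
    partitions <- make_partitions(y$axis, k, test = FALSE,
                                  min_segment = config$tmax - config$tmin)
  }
  if (partitions$n_samples != y$axis$n_samples) {
    stop("partitions were built for a different axis", call. = FALSE)
  }

  if (config$scale_data) {
    nrm <- normalize_inputs(y, xs, config$error)
  } else {
    x <- stack_predictors(xs)
    stop_if_not_aligned(y$axis, x$axis, "response and predictors")
    nrm <- list(y = y, x = x,
                scale_info = list(mu_y = rep(0, n_components(y)),
                                  s_y = rep(1, n_components(y)),
                                  mu_x = rep(0, n_components(x)),
                                  s_x = rep(1, n_components(x)),
                                  error = config$error))
  }
  p <- n_components(nrm$x)
  B <- if (config$basis > 0) {
    basis_matrix(L, config$basis, tstep, config$basis_window)
  } else NULL
  Z <- build_design(nrm$x$values, lag_samples, B)
  Yn <- t(nrm$y$values)
  comp_of_col <- rep(seq_len(p) - 1L, each = L)

  run_coefs <- list()
  run_hist <- list()
  test_pred <- if (partitions$test) matrix(NA_real_, nrow(Yn), ncol(Yn)) else NULL
  for (j in seq_along(partitions$runs)) {
    run <- partitions$runs[[j]]
    res <- run_boost(Z, Yn, partitions, run, config, comp_of_col)
    run_coefs[[j]] <- res$coefs
    run_hist[[j]] <- res$histories
    if (partitions$test) {
      te <- segment_samples(partitions, run$test)
      test_pred[te, ] <- Z[te, , drop = FALSE] %*% res$coefs
    }
  }

  # average run kernels (normalized units), then back-transform
  coefs_avg <- Reduce(`+`, run_coefs) / length(run_coefs)
  h_norm <- coefs_to_kernel_values(coefs_avg, p, L, B)
  si <- nrm$scale_info
  h_orig <- h_norm
  for (i in seq_len(p)) {
    for (ch in seq_len(n_components(y))) {
      h_orig[i, , ch] <- h_norm[i, , ch] * si$s_y[ch] / si$s_x[i]
    }
  }
  kernel <- trf_kernel(h_orig, config$tmin, tstep,
                       predictor_labels = nrm$x$labels,
                       channel_labels = y$labels, scale_info = si)

  exclude <- if (config$exclude_onset) {
    as.integer(round((config$tmax - config$tmin) / tstep))
  } else 0L
  if (partitions$test) {
    pe <- pe_from_matrices(Yn, test_pred, config$error, exclude)
    resid_err <- err_per_channel(Yn - test_pred, config$error)
    cross_validated <- TRUE
    predicted <- time_series(t(test_pred * rep(si$s_y, each = nrow(test_pred)) +
                                 rep(si$mu_y, each = nrow(test_pred))),
                             y$axis, y$labels, kind = "channel")
  } else {
    yhat <- Z %*% coefs_avg
    pe <- pe_from_matrices(Yn, yhat, config$error, exclude)
    resid_err <- err_per_channel(Yn - yhat, config$error)
    cross_validated <- FALSE
    predicted <- NULL
  }
  names(pe) <- y$labels
  names(resid_err) <- y$labels

  structure(
    list(kernel = kernel,
         proportion_explained = pe,
         residual_error = resid_err,
         cross_validated = cross_validated,
         history = history_tibble(run_hist, y$labels, nrm$x$labels, L,
                                  lag_samples, tstep),
         config = config, partitions = partitions,
         run_coefs = run_coefs, basis = B, lag_samples = lag_samples,
         predicted = predicted),
    class = "trf_fit"
  )
}

#' @export
print.trf_fit <- function(x, ...) {
  cat("<trf_fit>", if (x$cross_validated) "cross-validated" else "training-data metrics", "\n")
  print(x$kernel)
  cat("  proportion explained:",
      paste(sprintf("%s = %.4f", names(x$proportion_explained),
                    x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}

err_per_channel <- function(R, error) {
  if (error == "l2") colSums(R^2) else colSums(abs(R))
}

pe_from_matrices <- function(Y, Yhat, error, exclude = 0L) {
  if (exclude > 0L) {
    Y <- Y[-seq_len(exclude), , drop = FALSE]
    Yhat <- Yhat[-seq_len(exclude), , drop = FALSE]
  }
  num <- err_per_channel(Y - Yhat, error)
  cen <- sweep(Y, 2L, colMeans(Y))
  den <- err_per_channel(cen, error)
  if (any(den == 0)) stop("response channel with zero variability", call. = FALSE)
  1 - num / den
}

#' Proportion of variability explained
#'
#' Per channel, `1 - E(y - yhat) / E(y - mean(y))` with `E` the sum of
#' squares (l2) or of absolute values (l1). Equals 1 for a perfect
#' prediction, 0 for predicting the mean, and can be negative for predictions
#' worse than the mean.
#'
#' @param y,y_hat Aligned [time_series()].
#' @param error `"l2"` or `"l1"`.
#' @return Named numeric vector, one value per channel.
#' @export
proportion_explained <- function(y, y_hat, error = c("l2", "l1")) {
  error <- match.arg(error)
  stop_if_not_aligned(y$axis, y_hat$axis)
  pe <- pe_from_matrices(t(y$values), t(y_hat$values), error)
  names(pe) <- y$labels
  pe
}

#' Predict a response from a fitted kernel
#'
#' Applies the original-units kernel to original-units predictors, restoring
#' the intercept implied by the centering used during fitting:
#' `yhat = mu_y + sum_i conv(h_i, x_i - mu_x_i)`.
#'
#' @param object A [trf_kernel()] with `scale_info` (as produced by
#'   [boost_fit()]), or a plain kernel (no intercept handling).
#' @param predictors Aligned predictor [time_series()].
#' @param ... Unused.
#' @return A predicted `time_series`.
#' @export
predict.trf_kernel <- function(object, predictors, ...) {
  predictors <- stack_predictors(predictors)
  si <- object$scale_info
  if (!is.null(si)) {
    x <- with_values(predictors, predictors$values - si$mu_x)
    out <- convolve_mtrf(x, object)
    with_values(out, out$values + si$mu_y)
  } else {
    convolve_mtrf(predictors, object)
  }
}

#' @rdname predict.trf_kernel
#' @export
predict.trf_fit <- function(object, predictors, ...) {
  predict(object$kernel, predictors, ...)
}

#' Cross-validated mTRF fit
#'
#' Runs [boost_fit()] with a k-fold train/validation/test partition: for each
#' run the model is estimated on the train and validation segments and the
#' held-out test segment is predicted with that run's kernel. The test
#' predictions of all runs tile the full series (every sample is predicted
#' exactly once), and the reported predictive power is computed on this
#' concatenation — an unbiased estimate on unseen data.
#'
#' @inheritParams boost_fit
#' @param k Fold count (default 5); at least 3.
#' @return A `trf_fit` with `cross_validated = TRUE` and the concatenated
#'   test prediction in `$predicted`.
#' @export
cross_validate <- function(y, xs, config, k = 5L, partitions = NULL) {
  if (is.null(partitions)) {
    partitions <- make_partitions(y$axis, k, test = TRUE,
                                  min_segment = config$tmax - config$tmin)
  }
  if (!partitions$test) {
    stop("`partitions` must include a test set (make_partitions(..., test = TRUE))",
         call. = FALSE)
  }
  boost_fit(y, xs, config, partitions = partitions)
}

#' Compare the predictive power of two models
#'
#' Fits two predictor sets with identical partitions and returns the
#' per-channel difference in cross-validated predictive power,
#' `power(B) - power(A)`. Kernels are re-estimated for each model, because
#' mTRFs depend on which other predictors are present.
#'
#' @param y Response [time_series()].
#' @param xs_a,xs_b Predictor sets (each a `time_series` or list).
#' @param config A [boost_config()].
#' @param k Fold count when `partitions` is not given.
#' @param partitions Optional shared [make_partitions()] spec with a test set.
#' @return A list with `delta` (named per-channel power difference), `table`
#'   (tibble with per-channel powers) and both fits (`fit_a`, `fit_b`).
#' @export
compare_models <- function(y, xs_a, xs_b, config, k = 5L, partitions = NULL) {
  if (is.null(partitions)) {
    partitions <- make_partitions(y$axis, k, test = TRUE,
                                  min_segment = config$tmax - config$tmin)
  }
  fit_a <- cross_validate(y, xs_a, config, partitions = partitions)
  fit_b <- cross_validate(y, xs_b, config, partitions = partitions)
  delta <- fit_b$proportion_explained - fit_a$proportion_explained
  list(delta = delta,
       table = tibble::tibble(channel = names(delta),
                              power_a = unname(fit_a$proportion_explained),
                              power_b = unname(fit_b$proportion_explained),
                              delta = unname(delta)),
       fit_a = fit_a, fit_b = fit_b)
}

#' Backward (decoding) model
#'
#' Reconstructs a single stimulus feature from the multichannel response:
#' the same algorithm with the roles swapped, so all response channels
#' jointly predict the stimulus. Because each point of the response reflects
#' the stimulus *preceding* it, the lag window must extend into negative
#' delays (e.g. `tmin = -0.5, tmax = 0`).
#'
#' @param stimulus_feature Single-component [time_series()] to reconstruct.
#' @param response Multichannel response `time_series` (the predictors here).
#' @param config A [boost_config()] whose window allows negative lags.
#' @param ... Passed to [boost_fit()] or [cross_validate()].
#' @param cross_validated Use a test set and held-out metrics.
#' @return A `trf_fit`; the kernel has one TRF per response channel.
#' @export
fit_backward <- function(stimulus_feature, response, config,
                         cross_validated = FALSE, ...) {
  if (config$tmin >= 0) {
    stop("a backward model needs negative lags (tmin < 0)", call. = FALSE)
  }
  if (cross_validated) {
    cross_validate(stimulus_feature, response, config, ...)
  } else {
    boost_fit(stimulus_feature, response, config, ...)
  }
}
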
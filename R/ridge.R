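#' Ridge-regression mTRF (reference estimator)
#'
#' Closed-form Tikhonov-regularized estimate on the lagged design matrix
#' (columns = predictor x lag, same half-open lag convention and zero-padding
#' as [boost_fit()]): `h = (X'X + lambda I)^-1 X'y` per channel. Ridge
#' distributes kernel power over all lags (a smoothness prior), in contrast
#' to boosting's sparsity prior — with `lambda > 0` the ridge kernel almost
#' surely contains no exact zeros.
#'
#' With a `lambda` grid, the regularization weight is chosen by k-fold
#' cross-validated predictive power (each contiguous segment predicted from a
#' model fitted on the others), and the winning `lambda` is refitted on all
#' data.
#'
#' @param y Response [time_series()].
#' @param xs Predictor `time_series` or list.
#' @param tmin,tmax Lag window in seconds (half-open).
#' @param lambda Regularization weight (scalar >= 0) or grid for selection.
#' @param k Folds for grid selection (default 10).
#' @param scale_data Center and scale as in [normalize_inputs()].
#' @return A [trf_kernel()] in original units, with attributes `lambda`
#'   (chosen value) and `cv_power` (mean held-out power per grid value, when
#'   a grid was supplied).
#' @export
ridge_mtrf <- function(y, xs, tmin, tmax, lambda = 0, k = 10L,
                       scale_data = TRUE) {
  stopifnot(inherits(y, "time_series"))
  if (any(lambda < 0)) stop("`lambda` must be >= 0", call. = FALSE)
  tstep <- y$axis$tstep
  cfg <- boost_config(tmin, tmax) # reuse lag bookkeeping/validation
  lag_samples <- resolve_lags(cfg, tstep)
  L <- length(lag_samples)

  if (scale_data) {
    nrm <- normalize_inputs(y, xs, "l2")
  } else {
    x <- stack_predictors(xs)
    stop_if_not_aligned(y$axis, x$axis, "response and predictors")
    nrm <- list(y = y, x = x,
                scale_info = list(mu_y = rep(0, n_components(y)),
                                  s_y = rep(1, n_components(y)),
                                  mu_x = rep(0, n_components(x)),
                                  s_x = rep(1, n_components(x)), error = "l2"))
  }
  p <- n_components(nrm$x)
  Z <- build_design(nrm$x$values, lag_samples)
  Yn <- t(nrm$y$values)
  J <- ncol(Z)

  solve_ridge <- function(G, XtY, lam) {
    out <- tryCatch(solve(G + diag(lam, J), XtY), error = function(e) NULL)
    if (is.null(out)) {
      stop("singular lagged design at lambda = ", lam,
           " (collinear predictors); use lambda > 0", call. = FALSE)
    }
    out
  }

  cv_power <- NULL
  if (length(lambda) > 1L) {
    parts <- make_partitions(y$axis, k, test = FALSE, min_segment = tmax - tmin)
    cv_power <- numeric(length(lambda))
    seg_stats <- lapply(seq_len(k), function(j) {
      idx <- segment_samples(parts, j)
      Zi <- Z[idx, , drop = FALSE]
      list(idx = idx, G = crossprod(Zi), XtY = crossprod(Zi, Yn[idx, , drop = FALSE]))
    })
    G_all <- Reduce(`+`, lapply(seg_stats, `[[`, "G"))
    XtY_all <- Reduce(`+`, lapply(seg_stats, `[[`, "XtY"))
    for (li in seq_along(lambda)) {
      sse <- 0
      sst <- 0
      for (j in seq_len(k)) {
        W <- solve_ridge(G_all - seg_stats[[j]]$G, XtY_all - seg_stats[[j]]$XtY,
                         lambda[li])
        idx <- seg_stats[[j]]$idx
        R <- Yn[idx, , drop = FALSE] - Z[idx, , drop = FALSE] %*% W
        Yc <- sweep(Yn[idx, , drop = FALSE], 2L, colMeans(Yn[idx, , drop = FALSE]))
        sse <- sse + sum(R^2)
        sst <- sst + sum(Yc^2)
      }
      cv_power[li] <- 1 - sse / sst
    }
    lambda_best <- lambda[which.max(cv_power)]
  } else {
    lambda_best <- lambda
    G_all <- crossprod(Z)
    XtY_all <- crossprod(Z, Yn)
  }
  W <- solve_ridge(G_all, XtY_all, lambda_best)

  h_norm <- coefs_to_kernel_values(W, p, L)
  si <- nrm$scale_info
  h_orig <- h_norm
  for (i in seq_len(p)) {
    for (ch in seq_len(n_components(y))) {
      h_orig[i, , ch] <- h_norm[i, , ch] * si$s_y[ch] / si$s_x[i]
    }
  }
  kernel <- trf_kernel(h_orig, tmin, tstep, predictor_labels = nrm$x$labels,
                       channel_labels = y$labels, scale_info = si)
  attr(kernel, "lambda") <- lambda_best
  attr(kernel, "cv_power") <- cv_power
  kernel
}
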
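#' Multivariate temporal response function (mTRF) kernel
#'
#' A kernel maps predictor components to output channels across time lags:
#' entry `values[i, l, c]` is the weight with which predictor `i`, delayed by
#' the `l`-th lag, contributes to channel `c`. Lags live on a half-open window
#' `[tmin, tmax)` sampled at the response rate, so a window of (0, 0.5) s at
#' 100 Hz has exactly 50 lag bins.
#'
#' @param values Numeric array `(component, lag, channel)`. A matrix is
#'   treated as a single-channel kernel.
#' @param tmin Left edge of the lag window in seconds (inclusive).
#' @param tstep Lag sampling interval in seconds (the response `tstep`).
#' @param predictor_labels,channel_labels Component names.
#' @param scale_info Optional list of normalization records (see
#'   [normalize_inputs()]), allowing predictions in original units.
#' @return An object of class `trf_kernel`.
#' @export
trf_kernel <- function(values, tmin, tstep, predictor_labels = NULL,
                       channel_labels = NULL, scale_info = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a (component, lag, channel) array", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("kernel values must be finite", call. = FALSE)
  }
  d <- dim(values)
  if (is.null(predictor_labels)) predictor_labels <- paste0("x", seq_len(d[1L]))
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[3L]))
  stopifnot(length(predictor_labels) == d[1L], length(channel_labels) == d[3L])
  structure(
    list(values = values,
         lag_axis = time_axis(tmin, tstep, d[2L]),
         predictor_labels = as.character(predictor_labels),
         channel_labels = as.character(channel_labels),
         scale_info = scale_info,
         zero_fraction = mean(values == 0)),
    class = "trf_kernel"
  )
}

#' @export
print.trf_kernel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<trf_kernel> %d predictor(s) x %d lags x %d channel(s); lags [%g, %g) s; %.1f%% zeros\n",
    d[1L], d[2L], d[3L], x$lag_axis$tstart,
    x$lag_axis$tstart + d[2L] * x$lag_axis$tstep, 100 * x$zero_fraction))
  invisible(x)
}

#' Number of lag bins for a half-open lag window
#'
#' @param tmin,tmax Lag window edges in seconds, `tmin < tmax`.
#' @param tstep Lag sampling interval in seconds.
#' @return Integer count of lags in `[tmin, tmax)`.
#' @export
n_lags <- function(tmin, tmax, tstep) {
  if (tmin >= tmax) stop("`tmin` must be smaller than `tmax`", call. = FALSE)
  as.integer(round((tmax - tmin) / tstep))
}

# integer lag offsets (in samples) of a kernel
kernel_lag_samples <- function(kernel) {
  as.integer(round(kernel$lag_axis$tstart / kernel$lag_axis$tstep)) +
    seq_len(kernel$lag_axis$n_samples) - 1L
}

#' Convolve predictors with an mTRF kernel
#'
#' Computes the predicted response
#' `yhat[t] = sum_i sum_tau h[i, tau] * x[i, t - tau]` for every output
#' channel, with zero-padding where `t - tau` falls outside the predictor
#' (samples before the start and after the end contribute 0). The output is on
#' the predictor's axis.
#'
#' @param predictors A [time_series()] whose component count matches the
#'   kernel's predictor count, on the axis the kernel was estimated for.
#' @param kernel A [trf_kernel()].
#' @return A `time_series` of predicted channels.
#' @export
convolve_mtrf <- function(predictors, kernel) {
  stopifnot(inherits(predictors, "time_series"), inherits(kernel, "trf_kernel"))
  d <- dim(kernel$values)
  if (n_components(predictors) != d[1L]) {
    stop(sprintf("kernel expects %d predictor component(s), got %d",
                 d[1L], n_components(predictors)), call. = FALSE)
  }
  if (abs(predictors$axis$tstep - kernel$lag_axis$tstep) > 1e-9) {
    stop("predictor tstep does not match the kernel lag tstep", call. = FALSE)
  }
  n <- predictors$axis$n_samples
  lag0 <- as.integer(round(kernel$lag_axis$tstart / kernel$lag_axis$tstep))
  out <- matrix(0, d[3L], n)
  for (ch in seq_len(d[3L])) {
    acc <- numeric(n)
    for (i in seq_len(d[1L])) {
      h <- kernel$values[i, , ch]
      if (all(h == 0)) next
      z <- fft_convolve(predictors$values[i, ], h)
      # yhat[t] = z[t - lag0]
      t_idx <- seq_len(n)
      src <- t_idx - lag0
      ok <- src >= 1L & src <= length(z)
      acc[t_idx[ok]] <- acc[t_idx[ok]] + z[src[ok]]
    }
    out[ch, ] <- acc
  }
  time_series(out, predictors$axis, kernel$channel_labels, kind = "channel")
}

#' Event-locked averaging (ERP-style)
#'
#' Averages response segments around discrete events, the classical
#' event-related-potential estimate that the TRF generalizes. Events whose
#' window `[onset + tmin, onset + tmax)` does not fit inside the recording are
#' dropped; the dropped count is reported as an attribute.
#'
#' @param response A [time_series()] of kind channel.
#' @param events An [event_table()].
#' @param tmin,tmax Window edges relative to each event, in seconds
#'   (half-open, sampled at the response rate).
#' @return A channels-by-relative-time matrix with attributes `times`
#'   (relative timestamps) and `n_dropped`.
#' @export
epoch_average <- function(response, events, tmin, tmax) {
  stopifnot(inherits(response, "time_series"))
  tstep <- response$axis$tstep
  n_rel <- n_lags(tmin, tmax, tstep)
  off0 <- as.integer(round(tmin / tstep))
  n <- response$axis$n_samples
  centers <- event_sample_index(events$onset, response$axis)
  first <- centers + off0
  ok <- !is.na(centers) & first >= 1L & (first + n_rel - 1L) <= n
  if (!any(ok)) stop("no event has its full window inside the recording", call. = FALSE)
  segs <- lapply(which(ok), function(j) {
    response$values[, first[j]:(first[j] + n_rel - 1L), drop = FALSE]
  })
  avg <- Reduce(`+`, segs) / length(segs)
  rownames(avg) <- response$labels
  attr(avg, "times") <- tmin + (seq_len(n_rel) - 1L) * tstep
  attr(avg, "n_dropped") <- sum(!ok)
  avg
}

# Nearest-sample index for event times; ties (exactly half a sample) go to the
# earlier sample. Events outside the axis return NA.
event_sample_index <- function(times, axis) {
  pos <- (times - axis$tstart) / axis$tstep
  idx <- floor(pos + 0.5 + 1e-12)
  # ties toward earlier: a position of k + 0.5 exactly maps to k
  tie <- abs(pos - (floor(pos) + 0.5)) < 1e-9
  idx[tie] <- floor(pos[tie])
  idx <- as.integer(idx) + 1L
  idx[idx < 1L | idx > axis$n_samples] <- NA_integer_
  idx
}
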
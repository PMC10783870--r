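#' Spectrogram container
#'
#' A spectrogram is a band-kind [time_series()] carrying the center frequency
#' of each band. Values are non-negative energies until a response-scale
#' transform is applied.
#'
#' @param values Bands-by-time numeric matrix, non-negative.
#' @param axis A [time_axis()].
#' @param band_centers Strictly increasing center frequencies in Hz.
#' @return An object of class `spectrogram` (also a `time_series`).
#' @export
spectrogram <- function(values, axis, band_centers) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  stopifnot(length(band_centers) == nrow(values))
  if (any(diff(band_centers) <= 0)) {
    stop("`band_centers` must be strictly increasing", call. = FALSE)
  }
  ts <- time_series(values, axis,
                    labels = make.unique(sprintf("%.0fHz", band_centers),
                                         sep = "_"),
                    kind = "band")
  ts$band_centers <- as.numeric(band_centers)
  class(ts) <- c("spectrogram", class(ts))
  ts
}

# Equivalent rectangular bandwidth (Glasberg & Moore) at frequency f (Hz)
erb_bandwidth <- function(f) 24.7 + f / 9.26449

# ERB-rate-spaced center frequencies in [fmin, fmax], increasing
erb_space <- function(fmin, fmax, n) {
  ear_q <- 9.26449
  min_bw <- 24.7
  k <- ear_q * min_bw
  rev(-k + exp(seq_len(n) * (-log(fmax + k) + log(fmin + k)) / n) * (fmax + k))
}

#' Gammatone spectrogram of a sound waveform
#'
#' Models the cochlear decomposition of the acoustic signal: a bank of
#' 4th-order gammatone filters on ERB-rate-spaced center frequencies. The
#' per-band envelope is the magnitude (absolute value) of each filter's
#' output, averaged within non-overlapping frames of `1/frame_rate` seconds.
#'
#' The defaults (256 filters spanning 20-5000 Hz, framed at 1000 Hz) give a
#' high-resolution bank intended to be reduced with [bin_bands()] (eight
#' analysis bands is the usual compromise) and resampled to the analysis rate.
#'
#' @param wave A single-component [time_series()] holding mono audio.
#' @param n_filters Number of gammatone filters.
#' @param fmin,fmax Filterbank frequency range in Hz; `fmax` must be below the
#'   audio Nyquist frequency.
#' @param frame_rate Output frame rate in Hz.
#' @return A [spectrogram()] at `frame_rate`.
#' @export
gammatone_spectrogram <- function(wave, n_filters = 256L, fmin = 20, fmax = 5000,
                                  frame_rate = 1000) {
  stopifnot(inherits(wave, "time_series"))
  if (n_components(wave) != 1L) {
    stop("`wave` must be mono (single component); downmix first", call. = FALSE)
  }
  fs <- sampling_rate(wave)
  if (fmax >= fs / 2) stop("`fmax` must be below the audio Nyquist frequency", call. = FALSE)
  if (fmin >= fmax) stop("`fmin` must be below `fmax`", call. = FALSE)
  cf <- erb_space(fmin, fmax, n_filters)
  x <- wave$values[1L, ]
  n <- length(x)
  frame_len <- fs / frame_rate
  if (frame_len < 1) stop("`frame_rate` exceeds the audio sampling rate", call. = FALSE)
  n_frames <- max(1L, floor(n / frame_len))
  # FIR gammatone impulse responses, long enough for the slowest filter to decay
  out <- matrix(0, n_filters, n_frames)
  xf <- stats::fft(c(x, numeric(stats::nextn(2L * n, 2) - n)))
  nfft <- length(xf)
  t_ir <- (seq_len(nfft) - 1L) / fs
  for (b in seq_len(n_filters)) {
    bw <- 1.019 * erb_bandwidth(cf[b])
    len <- min(nfft, ceiling(fs * min(0.25, 12 / (2 * pi * bw))))
    tt <- t_ir[seq_len(len)]
    ir <- tt^3 * exp(-2 * pi * bw * tt) * cos(2 * pi * cf[b] * tt)
    peak <- max(abs(Re(stats::fft(c(ir, numeric(nfft - len))))[seq_len(nfft / 2)]))
    ir <- ir / peak # unit passband gain at the center frequency
    y <- Re(stats::fft(xf * stats::fft(c(ir, numeric(nfft - len))), inverse = TRUE)) / nfft
    env <- abs(y[seq_len(n)])
    # average within non-overlapping frames
    idx <- pmin(n_frames, floor((seq_len(n) - 1L) / frame_len) + 1L)
    keep <- idx <= n_frames
    out[b, ] <- as.numeric(tapply(env[keep], idx[keep], mean))
  }
  spectrogram(out, time_axis(wave$axis$tstart, 1 / frame_rate, n_frames), cf)
}

#' Bin spectrogram bands
#'
#' Reduces a high-resolution spectrogram to `n_bins` bands by summing
#' contiguous, near-equal-size groups of bands. Total power is conserved: the
#' sum over bands at every sample is unchanged. New band centers are the
#' geometric means of each group's centers.
#'
#' @param sgram A [spectrogram()].
#' @param n_bins Target band count, between 1 and the current band count.
#' @return A [spectrogram()] with `n_bins` bands.
#' @export
bin_bands <- function(sgram, n_bins) {
  stopifnot(inherits(sgram, "spectrogram"))
  n_bins <- as.integer(n_bins)
  nb <- n_components(sgram)
  if (is.na(n_bins) || n_bins < 1L) stop("`n_bins` must be at least 1", call. = FALSE)
  if (n_bins > nb) stop("`n_bins` exceeds the band count", call. = FALSE)
  if (n_bins == nb) return(sgram)
  groups <- split(seq_len(nb), ((seq_len(nb) - 1L) * n_bins) %/% nb + 1L)
  values <- do.call(rbind, lapply(groups, function(g) {
    colSums(sgram$values[g, , drop = FALSE])
  }))
  centers <- vapply(groups, function(g) exp(mean(log(sgram$band_centers[g]))), 0)
  spectrogram(values, sgram$axis, centers)
}

#' Broadband envelope of a spectrogram
#'
#' The acoustic envelope: per-sample sum of energy across all frequency bands,
#' the one-band extreme of [bin_bands()].
#'
#' @param sgram A [spectrogram()].
#' @return A single-component [time_series()] labelled `"envelope"`.
#' @export
sgram_envelope <- function(sgram) {
  stopifnot(inherits(sgram, "spectrogram"))
  time_series(colSums(sgram$values), sgram$axis, "envelope", kind = "scalar")
}

#' Nonlinear response-scale transforms
#'
#' Neural responses grow nonlinearly with acoustic power; candidate scales are
#' compared by transforming the predictor and keeping the model linear.
#' `"linear"` is the identity; `"power"` raises values to `exponent`
#' (conventionally 1/3); `"log"` maps to dB relative to the spectrogram
#' maximum, clipped at `floor_db` and shifted so the floor maps to 0 (the
#' maximum then maps to `-floor_db`), which keeps zeros finite.
#'
#' @param sgram A [spectrogram()] with non-negative values.
#' @param mode One of `"linear"`, `"power"`, `"log"`.
#' @param exponent Power-law exponent in (0, 1]; default 1/3.
#' @param floor_db Log-mode floor in dB relative to the maximum; negative.
#' @return The transformed [spectrogram()].
#' @export
apply_scale <- function(sgram, mode = c("linear", "power", "log"),
                        exponent = 1 / 3, floor_db = -50) {
  stopifnot(inherits(sgram, "spectrogram"))
  mode <- match.arg(mode)
  v <- sgram$values
  if (any(v < 0)) stop("response-scale transforms require non-negative values", call. = FALSE)
  out <- switch(mode,
    linear = v,
    power = {
      if (exponent <= 0 || exponent > 1) stop("`exponent` must be in (0, 1]", call. = FALSE)
      v^exponent
    },
    log = {
      if (floor_db >= 0) stop("`floor_db` must be negative", call. = FALSE)
      ref <- max(v)
      if (ref == 0) {
        v # all-zero spectrogram stays zero
      } else {
        db <- 20 * log10(pmax(v / ref, 10^(floor_db / 20)))
        db - floor_db
      }
    })
  spectrogram(out, sgram$axis, sgram$band_centers)
}

#' Acoustic onset (edge-detection) spectrogram
#'
#' Auditory cortex responds prominently to acoustic onsets; this transform
#' marks rising edges per frequency band with a non-negative signal that is
#' zero for time-constant input. `"rectified_difference"` generalizes the
#' half-wave rectified derivative: the largest rectified increase
#' `max(0, x[t] - x[t - d])` over delays `d` up to `delay_span`.
#' `"delayed_inhibition"` subtracts an exponentially decaying trace of the
#' recent past (decay time constant = `delay_span`) before rectifying, a
#' coarse stand-in for neural onset models with delayed inhibition.
#'
#' @param sgram A [spectrogram()] (log or power scale recommended).
#' @param method `"rectified_difference"` or `"delayed_inhibition"`.
#' @param delay_span Maximum look-back in seconds; at least one sample.
#' @return A non-negative [spectrogram()] of onsets.
#' @export
onset_spectrogram <- function(sgram, method = c("rectified_difference",
                                                "delayed_inhibition"),
                              delay_span = 0.03) {
  stopifnot(inherits(sgram, "spectrogram"))
  method <- match.arg(method)
  tstep <- sgram$axis$tstep
  d_max <- floor(delay_span / tstep + 1e-9)
  if (d_max < 1L) stop("`delay_span` must cover at least one sample", call. = FALSE)
  v <- sgram$values
  n <- ncol(v)
  out <- matrix(0, nrow(v), n)
  if (method == "rectified_difference") {
    for (d in seq_len(d_max)) {
      if (d >= n) break
      idx <- (d + 1L):n
      diffd <- v[, idx, drop = FALSE] - v[, idx - d, drop = FALSE]
      out[, idx] <- pmax(out[, idx, drop = FALSE], pmax(diffd, 0))
    }
  } else {
    # weight 1 at the previous sample, decaying with the time constant, so
    # constant input is fully inhibited (zero output) after the transient
    decay <- exp(-((seq_len(d_max) - 1L) * tstep) / delay_span)
    trace <- matrix(-Inf, nrow(v), n)
    for (d in seq_len(d_max)) {
      if (d >= n) break
      idx <- (d + 1L):n
      trace[, idx] <- pmax(trace[, idx, drop = FALSE],
                           decay[d] * v[, idx - d, drop = FALSE])
    }
    ok <- is.finite(trace)
    out[ok] <- pmax(v[ok] - trace[ok], 0)
  }
  spectrogram(out, sgram$axis, sgram$band_centers)
}

#' Impulse predictor from an event table
#'
#' Places one impulse per event at the sample nearest the event time (ties go
#' to the earlier sample). With `use_values = FALSE` every impulse has
#' magnitude 1 (a constant response to every event); with `use_values = TRUE`
#' the magnitude is the event's value (e.g. the word's surprisal), predicting
#' responses that scale with that quantity. Events falling outside the axis
#' are dropped and counted; coincident events sum.
#'
#' @param events An [event_table()].
#' @param axis A [time_axis()] for the output series.
#' @param use_values Use each event's `value` as impulse magnitude.
#' @param label Component label for the output.
#' @return A single-component `time_series` with attribute `n_dropped`.
#' @export
impulse_predictor <- function(events, axis, use_values = FALSE,
                              label = "impulses") {
  x <- numeric(axis$n_samples)
  n_dropped <- 0L
  if (nrow(events)) {
    idx <- event_sample_index(events$onset, axis)
    ok <- !is.na(idx)
    n_dropped <- sum(!ok)
    mag <- if (use_values) events$value[ok] else rep(1.0, sum(ok))
    for (j in seq_along(mag)) x[idx[ok][j]] <- x[idx[ok][j]] + mag[j]
  }
  out <- time_series(x, axis, label, kind = "scalar")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Step predictor from paired onset/offset events
#'
#' Implements the linking hypothesis of a response sustained for the duration
#' of an event: the series holds the event's magnitude on `[onset, offset)`
#' and 0 elsewhere. Onsets and offsets are given as an event table plus a
#' parallel vector of offsets.
#'
#' @param events An [event_table()] of onsets (with magnitudes in `value`).
#' @param offsets Numeric vector of offset times, one per event, each at or
#'   after its onset.
#' @param axis A [time_axis()].
#' @param label Component label.
#' @return A single-component `time_series`.
#' @export
step_predictor <- function(events, offsets, axis, label = "steps") {
  stopifnot(length(offsets) == nrow(events))
  if (any(offsets < events$onset)) {
    stop("every offset must be at or after its onset", call. = FALSE)
  }
  x <- numeric(axis$n_samples)
  tt <- axis_times(axis)
  for (j in seq_len(nrow(events))) {
    inside <- tt >= events$onset[j] - 1e-12 & tt < offsets[j] - 1e-12
    x[inside] <- x[inside] + events$value[j]
  }
  time_series(x, axis, label, kind = "scalar")
}
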
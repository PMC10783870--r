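#' Resample a time series to a lower rate
#'
#' Anti-aliased downsampling for bringing responses and predictors to a common
#' analysis rate (typically 100 Hz for cortical work, giving a 2.5x guard band
#' above a 20 Hz low-pass edge). The series is low-passed in the frequency
#' domain with a cutoff at `0.4 * target_rate` and then reconstructed on the
#' new axis by Fourier resampling, so a band-limited signal is reproduced
#' exactly up to the cutoff.
#'
#' Upsampling is refused: the estimators never need it and silently inventing
#' samples invites aliasing mistakes.
#'
#' @param ts A [time_series()].
#' @param target_rate New sampling rate in Hz; must be positive and no larger
#'   than the current rate.
#' @return A `time_series` with `tstep = 1/target_rate` and the same `tstart`.
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * (0:999) / 1000), time_axis(0, 1e-3, 1000))
#' ts100 <- ts_resample(ts, 100)
#' ts100$axis$tstep
#' @export
ts_resample <- function(ts, target_rate) {
  stopifnot(inherits(ts, "time_series"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("`target_rate` must be a positive number", call. = FALSE)
  }
  rate <- sampling_rate(ts)
  if (target_rate > rate + 1e-9) {
    stop(sprintf("upsampling requested (%.6g Hz -> %.6g Hz); ts_resample only downsamples",
                 rate, target_rate), call. = FALSE)
  }
  if (abs(target_rate - rate) <= 1e-9) return(ts)
  n <- ts$axis$n_samples
  n_out <- max(1L, as.integer(round(n * target_rate / rate)))
  cutoff <- 0.4 * target_rate
  out <- t(apply(ts$values, 1L, fft_resample_1d, n_out = n_out, rate = rate,
                 cutoff = cutoff))
  if (n_out == 1L) out <- matrix(out, nrow = n_components(ts))
  time_series(out, time_axis(ts$axis$tstart, 1 / target_rate, n_out),
              ts$labels, ts$kind)
}

# Fourier-domain low-pass + resample of a single real signal.
fft_resample_1d <- function(x, n_out, rate, cutoff) {
  n <- length(x)
  if (n_out == n) return(x)
  spec <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * rate / n
  freqs <- pmin(freqs, rate - freqs) # two-sided
  # raised-cosine roll-off over 20% of the cutoff avoids heavy ringing
  lo <- 0.9 * cutoff
  gain <- ifelse(freqs <= lo, 1,
                 ifelse(freqs >= cutoff, 0,
                        0.5 * (1 + cos(pi * (freqs - lo) / (cutoff - lo)))))
  spec <- spec * gain
  # truncate the spectrum to the new length (n_out < n here)
  half <- floor(n_out / 2)
  new_spec <- complex(n_out)
  new_spec[1:(half + 1L)] <- spec[1:(half + 1L)]
  if (half >= 1L) {
    new_spec[(n_out - half + 1L):n_out] <- spec[(n - half + 1L):n]
  }
  if (n_out %% 2L == 0L) {
    # shared Nyquist bin: keep it real
    new_spec[half + 1L] <- Re(new_spec[half + 1L])
  }
  Re(stats::fft(new_spec, inverse = TRUE)) / n
}

#' Zero-phase band-pass filter
#'
#' FIR windowed-sinc (Hamming) band-pass applied with exact group-delay
#' compensation, so the output has zero phase shift: peak latencies in the
#' filtered signal are interpretable. The default analysis band for cortical
#' responses is 0.5-20 Hz, which also removes slow drifts (taking the place of
#' baseline correction) before kernel estimation.
#'
#' @param ts A [time_series()].
#' @param low,high Band edges in Hz, `0 <= low < high < Nyquist`. `low = 0`
#'   gives a pure low-pass.
#' @param order Optional FIR order (number of taps, made odd internally).
#'   Defaults to a length giving a transition band of half the lower edge (or
#'   a tenth of the upper edge for a low-pass).
#' @return The filtered `time_series`.
#' @export
ts_bandpass <- function(ts, low, high, order = NULL) {
  stopifnot(inherits(ts, "time_series"))
  rate <- sampling_rate(ts)
  nyq <- rate / 2
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || low >= high || high >= nyq) {
    stop(sprintf("band edges must satisfy 0 <= low < high < Nyquist (%.6g Hz)", nyq),
         call. = FALSE)
  }
  transition <- if (low > 0) low / 2 else high / 10
  if (is.null(order)) order <- ceiling(3.3 * rate / transition)
  order <- as.integer(order)
  if (order %% 2L == 0L) order <- order + 1L # odd taps: integer group delay, type-I
  h <- if (low > 0) {
    signal::fir1(order - 1L, c(low, high) / nyq, type = "pass")
  } else {
    signal::fir1(order - 1L, high / nyq, type = "low")
  }
  out <- t(apply(ts$values, 1L, fir_zerophase, h = h))
  if (ncol(ts$values) == 1L) out <- matrix(out, nrow = n_components(ts))
  with_values(ts, out)
}

# Apply a linear-phase FIR once and shift back by its (integer) group delay.
fir_zerophase <- function(x, h) {
  n <- length(x)
  delay <- (length(h) - 1L) / 2L
  padded <- c(x, numeric(length(h)))
  y <- fft_convolve(padded, h)
  y[(delay + 1L):(delay + n)]
}

# Linear convolution of two real vectors via FFT.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}
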
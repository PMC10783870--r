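#' Uniform time axis
#'
#' Describes a uniformly sampled time axis: sample `i` (0-based) has timestamp
#' `tstart + i * tstep`. All containers in trfboost (responses, predictors,
#' kernels) carry one of these, so that alignment between series can be checked
#' rather than assumed.
#'
#' @param tstart Time of the first sample in seconds.
#' @param tstep Sampling interval in seconds (`1 / rate`); must be positive.
#' @param n_samples Number of samples; must be at least 1.
#' @return An object of class `time_axis`.
#' @examples
#' ax <- time_axis(0, 0.01, 100) # 1 s at 100 Hz
#' axis_times(ax)[1:3]
#' @export
time_axis <- function(tstart, tstep, n_samples) {
  stopifnot(is.numeric(tstart), length(tstart) == 1L, is.finite(tstart))
  if (!is.numeric(tstep) || length(tstep) != 1L || !is.finite(tstep) || tstep <= 0) {
    stop("`tstep` must be a positive number", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    stop("`n_samples` must be at least 1", call. = FALSE)
  }
  structure(
    list(tstart = as.numeric(tstart), tstep = as.numeric(tstep),
         n_samples = n_samples),
    class = "time_axis"
  )
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d samples @ %.6g Hz, t = [%g, %g) s\n",
              x$n_samples, 1 / x$tstep, x$tstart,
              x$tstart + x$n_samples * x$tstep))
  invisible(x)
}

#' @rdname time_axis
#' @param axis A `time_axis`.
#' @export
axis_times <- function(axis) {
  axis$tstart + (seq_len(axis$n_samples) - 1L) * axis$tstep
}

#' @rdname time_axis
#' @param a,b Two `time_axis` objects.
#' @param tol Tolerance in seconds for comparing `tstart` and `tstep`.
#' @return `axes_aligned()` returns `TRUE` iff `tstart`, `tstep` and
#'   `n_samples` all agree within `tol`.
#' @export
axes_aligned <- function(a, b, tol = 1e-9) {
  abs(a$tstart - b$tstart) <= tol &&
    abs(a$tstep - b$tstep) <= tol &&
    a$n_samples == b$n_samples
}

stop_if_not_aligned <- function(a, b, what = "series") {
  if (!axes_aligned(a, b)) {
    stop("time axes of ", what, " are not aligned (tstart/tstep/n_samples must match)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Uniformly sampled multichannel time series
#'
#' The shared container for responses (component kind `"channel"`), predictor
#' banks (kind `"band"`) and single feature series (kind `"scalar"`). Values
#' are stored as a components-by-time numeric matrix.
#'
#' @param values Numeric matrix, components in rows, time in columns. A plain
#'   vector is treated as a single component.
#' @param axis A [time_axis()] whose `n_samples` matches `ncol(values)`.
#' @param labels Character vector of unique component labels; defaults to
#'   `"c1"`, `"c2"`, ...
#' @param kind One of `"channel"`, `"band"`, `"scalar"`.
#' @return An object of class `time_series`.
#' @examples
#' ts <- time_series(rbind(sin(1:100 / 10), cos(1:100 / 10)),
#'                   time_axis(0, 0.01, 100), c("Fz", "Cz"))
#' ts
#' @export
time_series <- function(values, axis, labels = NULL,
                        kind = c("channel", "band", "scalar")) {
  kind <- match.arg(kind)
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, nrow = 1L)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (components x time)", call. = FALSE)
  }
  if (!inherits(axis, "time_axis")) stop("`axis` must be a time_axis", call. = FALSE)
  if (ncol(values) != axis$n_samples) {
    stop(sprintf("`values` has %d time samples but axis has %d",
                 ncol(values), axis$n_samples), call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("c", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("`labels` length must equal the number of components", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("component labels must be unique", call. = FALSE)
  rownames(values) <- labels
  structure(
    list(values = values, axis = axis, labels = labels, kind = kind),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d %s component(s) x %d samples @ %.6g Hz\n",
              n_components(x), x$kind, x$axis$n_samples, 1 / x$axis$tstep))
  if (n_components(x) <= 8) cat("  components:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname time_series
#' @param ts A `time_series`.
#' @export
n_components <- function(ts) nrow(ts$values)

#' @rdname time_series
#' @export
sampling_rate <- function(ts) 1 / ts$axis$tstep

with_values <- function(ts, values) {
  time_series(values, time_axis(ts$axis$tstart, ts$axis$tstep, ncol(values)),
              ts$labels, ts$kind)
}

#' Combine predictor series into a single band stack
#'
#' Stacks one or several aligned [time_series()] into one multi-component
#' series, the form the estimators consume. Labels are made unique by
#' prefixing duplicated ones with the series index.
#'
#' @param xs A `time_series` or a list of aligned `time_series`.
#' @return A single `time_series` of kind `"band"`.
#' @export
stack_predictors <- function(xs) {
  if (inherits(xs, "time_series")) xs <- list(xs)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "time_series")))
  ax <- xs[[1L]]$axis
  for (x in xs[-1L]) stop_if_not_aligned(ax, x$axis, "predictors")
  values <- do.call(rbind, lapply(xs, function(x) x$values))
  labels <- unlist(lapply(xs, function(x) x$labels), use.names = FALSE)
  if (anyDuplicated(labels)) {
    labels <- unlist(lapply(seq_along(xs), function(i) {
      paste0("x", i, ".", xs[[i]]$labels)
    }), use.names = FALSE)
  }
  time_series(values, ax, labels, kind = "band")
}

#' Discrete stimulus events
#'
#' An event table holds discrete stimulus events: an onset time in seconds, a
#' real magnitude (for example a word's surprisal) and a label. Stored as a
#' tibble with columns `onset`, `value`, `label`.
#'
#' @param onset Numeric vector of event times in seconds, non-negative.
#' @param value Numeric magnitudes (default 1 for every event).
#' @param label Character labels (default `""`).
#' @return A tibble of class `event_table`, sorted by onset.
#' @examples
#' event_table(c(0.1, 0.25), value = c(2, 3))
#' @export
event_table <- function(onset = numeric(), value = NULL, label = NULL) {
  onset <- as.numeric(onset)
  if (length(onset) && any(!is.finite(onset))) {
    stop("event onsets must be finite", call. = FALSE)
  }
  if (length(onset) && any(onset < 0)) {
    stop("event onsets must be >= 0", call. = FALSE)
  }
  if (is.null(value)) value <- rep(1.0, length(onset))
  if (is.null(label)) label <- rep("", length(onset))
  stopifnot(length(value) == length(onset), length(label) == length(onset))
  ord <- order(onset)
  out <- tibble::tibble(onset = onset[ord], value = as.numeric(value)[ord],
                        label = as.character(label)[ord])
  class(out) <- c("event_table", class(out))
  out
}

#' Subtract a reference channel set
#'
#' Simple re-referencing helper: subtracts the mean over a designated set of
#' channels from every channel.
#'
#' @param ts A `time_series` of kind `"channel"`.
#' @param reference Character vector of channel labels to average as reference.
#' @return A re-referenced `time_series`.
#' @export
rereference <- function(ts, reference) {
  stopifnot(inherits(ts, "time_series"))
  missing <- setdiff(reference, ts$labels)
  if (length(missing)) {
    stop("unknown reference channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- colMeans(ts$values[reference, , drop = FALSE])
  with_values(ts, sweep(ts$values, 2L, ref))
}
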
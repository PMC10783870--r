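#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mTRF kernel into a long tibble
#'
#' One row per (predictor, lag, channel) kernel entry, convenient for
#' plotting and export.
#'
#' @param x A [trf_kernel()].
#' @param ... Unused.
#' @return A tibble with columns `predictor`, `lag`, `channel`, `value`.
#' @method tidy trf_kernel
#' @export
tidy.trf_kernel <- function(x, ...) {
  d <- dim(x$values)
  lags <- axis_times(x$lag_axis)
  tibble::tibble(
    predictor = rep(x$predictor_labels, times = d[2L] * d[3L]),
    lag = rep(rep(lags, each = d[1L]), times = d[3L]),
    channel = rep(x$channel_labels, each = d[1L] * d[2L]),
    value = as.vector(x$values)
  )
}

#' Tidy per-channel fit metrics
#'
#' @param x A `trf_fit`.
#' @param ... Unused.
#' @return A tibble with one row per channel.
#' @method tidy trf_fit
#' @export
tidy.trf_fit <- function(x, ...) {
  tibble::tibble(channel = names(x$proportion_explained),
                 proportion_explained = unname(x$proportion_explained),
                 residual_error = unname(x$residual_error))
}

#' One-row fit summary
#'
#' @param x A `trf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: mean/max predictive power, kernel sparsity,
#'   step count and whether metrics are cross-validated.
#' @method glance trf_fit
#' @export
glance.trf_fit <- function(x, ...) {
  tibble::tibble(
    mean_power = mean(x$proportion_explained),
    max_power = max(x$proportion_explained),
    zero_fraction = x$kernel$zero_fraction,
    n_steps = nrow(x$history),
    cross_validated = x$cross_validated
  )
}

#' Plot a TRF kernel
#'
#' Lag profiles per predictor, one panel per channel. Requires ggplot2.
#'
#' @param object A [trf_kernel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.trf_kernel <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2", call. = FALSE)
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = lag, y = value, color = predictor)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "lag (s)", y = "kernel weight")
}

utils::globalVariables(c("lag", "value", "predictor", "channel"))
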
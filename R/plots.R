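# ggplot2 diagnostics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a z-score time series
#'
#' @param object an `rs_zscore` tibble from [zscore_series()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rs_zscore <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "time from event (ms)", y = "normalised rate (z)") +
    ggplot2::theme_minimal()
}

#' Plot a cross-correlogram
#'
#' Shows the smoothed raw CCG and, when present, the shift predictor and
#' the corrected correlogram.
#'
#' @param object an `rs_ccg` tibble from [ccg()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rs_ccg <- function(object, ...) {
  keep <- intersect(c("raw", "shift_predictor", "corrected"), names(object))
  long <- tidyr::pivot_longer(object[, c("lag_ms", keep)], -"lag_ms",
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_ms, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms): positive = second unit later",
                  y = "normalised coincidences") +
    ggplot2::theme_minimal()
}

#' Plot cluster-test t-values with significant clusters
#'
#' @param object an `rs_cluster_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rs_cluster_test <- function(object, ...) {
  df <- tibble::tibble(time_ms = object$time_ms, t = object$t_values,
                       significant = object$significant_mask)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-object$threshold, object$threshold),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "paired t") +
    ggplot2::theme_minimal()
  if (any(df$significant)) {
    p <- p + ggplot2::geom_point(
      data = df[df$significant, ],
      ggplot2::aes(y = 0), colour = "red", size = 0.4)
  }
  p
}
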
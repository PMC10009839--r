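#' Plot impact-score series
#'
#' Monthly shortage impact score per IG, one panel per IG.
#'
#' @param impact Tibble from [impact_series()].
#' @param igs Optional subset of IG codes.
#' @return A ggplot object.
#' @export
plot_impact_series <- function(impact, igs = NULL) {
  d <- if (is.null(igs)) impact else impact[impact$ig_code %in% igs, ]
  ggplot2::ggplot(d, ggplot2::aes(ym_first_day(.data$month), .data$score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ig_code)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "shortage impact score") +
    ggplot2::theme_minimal()
}

#' Histogram of forecast absolute errors
#'
#' Distribution of |actual - forecast| across forecast records.
#'
#' @param records ForecastRecord tibble.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_mae_histogram <- function(records, binwidth = 0.02) {
  ggplot2::ggplot(records,
                  ggplot2::aes(abs(.data$actual - .data$forecast))) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "absolute forecast error", y = "forecasts") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' The confusion matrix of binned actual vs forecast classes as a heatmap
#' with counts.
#'
#' @param object A `"shortage_eval"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shortage_eval
#' @export
autoplot.shortage_eval <- function(object, ...) {
  d <- as.data.frame(object$confusion$matrix)
  ggplot2::ggplot(d, ggplot2::aes(.data$forecast, .data$actual,
                                  fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "forecast class", y = "actual class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-importance table
#'
#' Percentage importance shares by feature family (bars), optionally split
#' by lag.
#'
#' @param object An `"importance_table"`.
#' @param by `"family"` or `"family_lag"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot importance_table
#' @export
autoplot.importance_table <- function(object, by = c("family", "family_lag"),
                                      ...) {
  by <- match.arg(by)
  d <- tidy(object, by = by)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$share,
                                       stats::reorder(.data$family, .data$share))) +
    ggplot2::labs(x = "importance share (%)", y = NULL) +
    ggplot2::theme_minimal()
  if (by == "family") {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$lag)),
                          position = "stack") +
      ggplot2::labs(fill = "lag")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
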
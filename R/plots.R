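#' Scatter plot of brain-age delta against chronological age
#'
#' The workhorse diagnostic for age-dependent bias: each point is a
#' subject, the solid line is the OLS fit of delta on age, and the dashed
#' line marks delta = 0. An unbiased arm shows a flat fitted line.
#'
#' @param predictions A prediction tibble.
#' @param adjusted Plot `delta_adjusted` instead of `delta`.
#' @param colour_by_group Colour points by the `group` column when present.
#' @return A ggplot object.
#' @export
plot_delta_age <- function(predictions, adjusted = FALSE,
                           colour_by_group = TRUE) {
  ycol <- if (adjusted) "delta_adjusted" else "delta"
  if (!ycol %in% names(predictions)) {
    abort_agebias(sprintf("Column `%s` not found.", ycol),
                  "agebias_input_error")
  }
  aes_pts <- if (colour_by_group && "group" %in% names(predictions)) {
    ggplot2::aes(x = .data$age, y = .data[[ycol]], colour = .data$group)
  } else {
    ggplot2::aes(x = .data$age, y = .data[[ycol]])
  }
  ggplot2::ggplot(predictions, aes_pts) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_smooth(ggplot2::aes(x = .data$age, y = .data[[ycol]]),
                         method = "lm", formula = y ~ x, colour = "black",
                         linewidth = 0.6, se = TRUE, inherit.aes = FALSE) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = sprintf("Brain-age delta%s (years)",
                              if (adjusted) " (adjusted)" else "")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of predicted against chronological age
#'
#' Shows predictions against the identity line `y = x` (dashed red) with
#' the fitted regression line; attenuated models have a fitted slope well
#' below 1.
#'
#' @inheritParams plot_delta_age
#' @return A ggplot object.
#' @export
plot_predicted_age <- function(predictions, adjusted = FALSE,
                               colour_by_group = TRUE) {
  ycol <- if (adjusted) "predicted_adjusted" else "predicted_raw"
  if (!ycol %in% names(predictions)) {
    abort_agebias(sprintf("Column `%s` not found.", ycol),
                  "agebias_input_error")
  }
  aes_pts <- if (colour_by_group && "group" %in% names(predictions)) {
    ggplot2::aes(x = .data$age, y = .data[[ycol]], colour = .data$group)
  } else {
    ggplot2::aes(x = .data$age, y = .data[[ycol]])
  }
  ggplot2::ggplot(predictions, aes_pts) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_smooth(ggplot2::aes(x = .data$age, y = .data[[ycol]]),
                         method = "lm", formula = y ~ x, colour = "black",
                         linewidth = 0.6, se = TRUE, inherit.aes = FALSE) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Predicted brain age (years)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-group mean deltas with bootstrap confidence intervals
#'
#' @param object A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$group_means,
                  ggplot2::aes(x = .data$group, y = .data$mean_delta)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean brain-age delta (years)") +
    ggplot2::theme_minimal()
}

#' Plot an experiment's delta-age panels for every arm
#'
#' @param object An `agebias_experiment` from [run_experiment()].
#' @param set `"train"` or `"test"`.
#' @param ... Unused.
#' @return A ggplot object, facetted by adjustment arm.
#' @method autoplot agebias_experiment
#' @export
autoplot.agebias_experiment <- function(object, set = c("test", "train"),
                                        ...) {
  set <- match.arg(set)
  tabs <- reproduce_figures(object)
  tabs <- dplyr::filter(tabs, .data$set == !!set, .data$panel == "delta")
  ggplot2::ggplot(tabs, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$lwr), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upr), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Brain-age delta (years)") +
    ggplot2::theme_minimal()
}
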
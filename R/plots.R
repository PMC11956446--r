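#' Plot a prior density
#'
#' @param object A `spline_prior` or `beta_prior`.
#' @param n Number of evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spline_prior <- function(object, n = 401, ...) {
  plot_prior_density(object, n = n)
}

#' @rdname autoplot.spline_prior
#' @export
autoplot.beta_prior <- function(object, n = 401, ...) {
  plot_prior_density(object, n = n)
}

plot_prior_density <- function(prior, n = 401) {
  x <- seq(0, 1, length.out = n)
  df <- tibble(rate = x, density = prior_density(prior, x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "event rate", y = "prior density",
                  subtitle = prior$informativeness) +
    ggplot2::theme_minimal()
}

#' Plot a grid posterior
#'
#' @param object A [grid_posterior()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_posterior <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rate, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rate", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot an estimated power curve
#'
#' Raw Monte Carlo estimates (points, with +-2 MC SE bars) and the
#' isotonic-smoothed curve used for size selection; the dashed line marks
#' the target power and the vertical line the chosen size.
#'
#' @param object A [sample_size_search()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_search <- function(object, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$power,
      ymin = pmax(.data$power - 2 * .data$mc_se, 0),
      ymax = pmin(.data$power + 2 * .data$mc_se, 1)
    )) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power_smoothed)) +
    ggplot2::geom_hline(yintercept = object$target_power, linetype = "dashed") +
    ggplot2::labs(x = "subjects per arm", y = "P(declare effect)") +
    ggplot2::theme_minimal()
  if (object$achieved) {
    p <- p + ggplot2::geom_vline(xintercept = object$n_selected, linetype = "dotted")
  }
  p
}

#' Plot operating characteristics
#'
#' Bar chart of the estimated indicators with +-2 MC SE error bars.
#'
#' @param object A [operating_characteristics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trial_oc <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indicator, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$estimate - 2 * .data$mc_se, 0),
      ymax = pmin(.data$estimate + 2 * .data$mc_se, 1)
    ), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of simulated trials") +
    ggplot2::theme_minimal()
}
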
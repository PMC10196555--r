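#' Plot a simulated resistance trajectory
#'
#' @param object A `resistance_trajectory` from [simulate_trajectory()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resistance_trajectory
#' @export
autoplot.resistance_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$p)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "Year", y = "Resistance allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot predicted trajectories under several refuge scenarios
#'
#' @param trajectories Output of [run_scenarios()] (columns `scenario`,
#'   `year`, `p`, optionally `observed`).
#' @param log_y Use a log10 y axis (default `FALSE`).
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, log_y = FALSE) {
  stopifnot(all(c("scenario", "year", "p") %in% names(trajectories)))
  gg <- ggplot2::ggplot(trajectories,
                        ggplot2::aes(x = .data$year, y = .data$p,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Resistance allele frequency",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
  if ("observed" %in% names(trajectories)) {
    obs <- dplyr::distinct(trajectories[!is.na(trajectories$observed),
                                        c("year", "observed")])
    gg <- gg + ggplot2::geom_point(
      data = obs, ggplot2::aes(x = .data$year, y = .data$observed),
      inherit.aes = FALSE, shape = 21, fill = "grey30"
    )
  }
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot annual monitoring estimates with confidence intervals
#'
#' @param annual Data frame with columns `year`, `mean`, `lower`, `upper`
#'   (e.g. bound rows of [annual_mean_bootstrap()] results).
#' @param log_y Use a log10 y axis (default `TRUE`, the usual display for
#'   frequencies spanning orders of magnitude).
#' @return A ggplot.
#' @export
plot_monitoring <- function(annual, log_y = TRUE) {
  stopifnot(all(c("year", "mean", "lower", "upper") %in% names(annual)))
  gg <- ggplot2::ggplot(annual, ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(x = "Year", y = "Mean frequency (95% CI)") +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' @describeIn log_linear_regression Scatter plot on a log10 y axis with
#'   the fitted line.
#' @param object A `log_lm`.
#' @method autoplot log_lm
#' @export
autoplot.log_lm <- function(object, ...) {
  d <- tibble::tibble(x = object$data[[object$x]], y = object$data[[object$y]])
  g <- glance(object)
  line <- tibble::tibble(x = range(d$x))
  line$y <- 10^(g$intercept + g$slope * line$x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "#b2182b") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$x, y = object$y) +
    ggplot2::theme_minimal()
}
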
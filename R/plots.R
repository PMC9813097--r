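#' Plot a setpoint regression
#'
#' Scatter of amplitude change vs immediate amplitude with the fitted
#' regression line, its 95% confidence band, the zero-change line and the
#' setpoint (x-axis zero-intercept) marked by a dashed vertical line.
#'
#' @param object An `okr_setpoint_fit` from [regress_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.okr_setpoint_fit <- function(object, ...) {
  band <- confidence_band(object)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$immediate_deg,
                                    y = .data$delta_deg)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$immediate_deg, ymin = .data$lwr_deg,
                   ymax = .data$upr_deg),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_line(
      data = band,
      ggplot2::aes(x = .data$immediate_deg, y = .data$fit_deg),
      inherit.aes = FALSE, linewidth = 0.8
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "immediate OKR amplitude I (deg, peak-to-peak)",
      y = "amplitude change E - I (deg)",
      title = sprintf("slope %.2f, R² %.2f%s",
                      object$slope, object$r_squared,
                      if (!is.na(object$x_zero_intercept)) {
                        sprintf(", setpoint %.1f°",
                                object$x_zero_intercept)
                      } else {
                        ""
                      })
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$x_zero_intercept)) {
    p <- p + ggplot2::geom_vline(xintercept = object$x_zero_intercept,
                                 linetype = "dashed")
  }
  p
}

#' Plot the population per-cycle amplitude time course
#'
#' @param pop A tibble from [population_cycle_average()].
#' @param period_s Optional cycle period to put time (min) on the x axis
#'   instead of cycle index.
#' @return A ggplot object.
#' @export
plot_population_average <- function(pop, period_s = NULL) {
  x <- if (is.null(period_s)) pop$cycle_index else
    pop$cycle_index * period_s / 60
  d <- dplyr::mutate(pop, x = x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$mean_pp_deg)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_pp_deg - .data$sd_pp_deg,
                   ymax = .data$mean_pp_deg + .data$sd_pp_deg),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (is.null(period_s)) "cycle index" else "training time (min)",
      y = "population mean peak-to-peak amplitude (deg)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a short segment of a recording
#'
#' Stimulus and eye traces over a time window; useful for inspecting
#' simulated or imported recordings.
#'
#' @param trace A trace tibble (raw or preprocessed).
#' @param from,to Time window, s.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, from = 0, to = 60) {
  d <- trace |>
    dplyr::filter(.data$time_s >= from, .data$time_s <= to) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("stim_deg", "left_deg", "right_deg", "eye_deg")),
      names_to = "series", values_to = "deg"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$deg,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
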
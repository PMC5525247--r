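# ggplot2 views of the main result types.

#' Plot a cumulative selectivity series
#'
#' @param series Tibble from [si_series()] (optionally with an `id` column
#'   to draw one line per animal).
#' @return A ggplot object.
#' @export
plot_si_series <- function(series) {
  mapping <- if ("id" %in% names(series)) {
    ggplot2::aes(x = .data$t_hours, y = .data$si, group = .data$id)
  } else {
    ggplot2::aes(x = .data$t_hours, y = .data$si)
  }
  ggplot2::ggplot(series, mapping) +
    ggplot2::geom_line(alpha = 0.7, na.rm = TRUE) +
    ggplot2::labs(x = "Time in experiment (h)", y = "Selectivity index (SI)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot group mean SI with its confidence band
#'
#' @param summary Tibble from [group_mean_si()].
#' @return A ggplot object.
#' @export
plot_group_si <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$t_hours, y = .data$mean_si,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Time in experiment (h)", y = "Mean SI",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the hourly activity series
#'
#' @param activity Tibble from [activity_per_hour()].
#' @return A ggplot object.
#' @export
plot_activity <- function(activity) {
  ggplot2::ggplot(activity,
                  ggplot2::aes(x = .data$hour_start, y = .data$n_reads)) +
    ggplot2::geom_col(width = 3000) +
    ggplot2::labs(x = "Clock time", y = "Antenna reads per hour") +
    ggplot2::theme_minimal()
}

#' Plot the preferred-cage series (preference blocks)
#'
#' @param series Tibble from [preferred_cage_series()].
#' @return A ggplot object.
#' @export
plot_preference_series <- function(series) {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$t_hours, y = .data$preferred)) +
    ggplot2::geom_point(shape = 15, size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "Time in experiment (h)", y = "Preferred cage") +
    ggplot2::theme_minimal()
}
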
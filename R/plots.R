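#' Distance-to-AP plot of simulated or tracked trajectories
#'
#' The standard congression readout: per-chromosome distance to the AP over
#' time, optionally colored by motion phase.
#'
#' @param data Trajectory tibble (`t_s`, coordinates, optional `state`).
#' @param p AP point (µm).
#' @return A ggplot object.
#' @export
plot_distance_to_ap <- function(data, p) {
  df <- distance_to_ap(data, p)
  df$track <- if ("oocyte" %in% names(df)) {
    interaction(df$oocyte, df$chromosome)
  } else if ("chromosome" %in% names(df)) {
    factor(df$chromosome)
  } else {
    factor(1)
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s / 60,
                                         y = .data$distance_um,
                                         group = .data$track))
  gg <- if ("state" %in% names(df)) {
    gg + ggplot2::geom_line(ggplot2::aes(color = .data$state), linewidth = 0.3)
  } else {
    gg + ggplot2::geom_line(alpha = 0.5, linewidth = 0.3)
  }
  gg + ggplot2::labs(x = "time after NEBD (min)",
                     y = "distance to AP (µm)")
}

#' @export
autoplot.congression_sim <- function(object, ...) {
  plot_distance_to_ap(object$trajectories, object$geometry$ap_point) +
    ggplot2::ggtitle(sprintf("model variant %d, seed %d",
                             object$params$model_variant, object$seed))
}

#' @export
autoplot.congression_cohort <- function(object, ...) {
  plot_distance_to_ap(object$trajectories, object$geometry$ap_point) +
    ggplot2::facet_wrap(~oocyte) +
    ggplot2::ggtitle(sprintf("model variant %d, %d oocytes",
                             object$params$model_variant,
                             object$n_oocytes))
}

#' Histogram of capture times
#'
#' @param object A `capture_stats` object from [capture_statistics()].
#' @param ... Unused.
#' @return A ggplot object (0.5-min bins by default of the statistics).
#' @export
autoplot.capture_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid_min, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_start_min[1:2]) *
                        0.9) +
    ggplot2::labs(x = "capture time after NEBD (min)", y = "events")
}

#' Normalized patch-intensity traces
#'
#' @param data Normalized trace tibble (`t_min`, `normalized`, optional
#'   `chromosome`).
#' @return A ggplot object with the background level marked.
#' @export
plot_intensity_traces <- function(data) {
  gg <- ggplot2::ggplot(data, ggplot2::aes(x = .data$t_min,
                                           y = .data$normalized))
  gg <- if ("chromosome" %in% names(data)) {
    gg + ggplot2::geom_line(ggplot2::aes(group = .data$chromosome),
                            alpha = 0.4)
  } else {
    gg + ggplot2::geom_line()
  }
  gg + ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "time after NEBD (min)",
                  y = "normalized patch intensity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
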
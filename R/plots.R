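## ggplot2 autoplot methods for the result objects.

#' Plot a per-phase metric decomposition
#'
#' @param object A `phase_fit` from [phase_metrics()].
#' @param metric One of `"mean_velocity_dps"`, `"net_distance_deg"`,
#'   `"start_position_deg"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_fit <- function(object, metric = "mean_velocity_dps", ...) {
  d <- object$phases
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "movement phase", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a pointwise |t|-score trace with its significance threshold
#'
#' @param object A `tscore_trace` from [pointwise_tscore()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tscore_trace <- function(object, ...) {
  d <- tibble::as_tibble(object)
  crit <- attr(object, "critical")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$t_abs)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = crit, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::geom_point(data = d[d$significant, ], color = "firebrick",
                        size = 0.4) +
    ggplot2::labs(x = "time (s)", y = "|t|",
                  subtitle = sprintf("df = %d, |t| > %.3f significant",
                                     attr(object, "df"), crit)) +
    ggplot2::theme_minimal()
}

#' Plot a peri-stimulus time histogram
#'
#' @param object An `epoch_response` from [epoch_response()].
#' @param ... Unused.
#' @return A ggplot object (mean spike count per bin vs. time from onset).
#' @exportS3Method ggplot2::autoplot
autoplot.epoch_response <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(object$psth,
                  ggplot2::aes(x = .data$bin_start_s, y = .data$mean_count)) +
    ggplot2::geom_col(width = w$bin_s, fill = "grey30") +
    ggplot2::annotate("rect", xmin = 0, xmax = w$peri_s, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "dodgerblue") +
    ggplot2::labs(x = "time from stimulation onset (s)",
                  y = sprintf("mean spikes / %g ms bin", 1000 * w$bin_s)) +
    ggplot2::theme_minimal()
}

#' Plot a cycle average with its SEM ribbon
#'
#' @param object A `cycle_average` from [fold_cycles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_average <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phase, y = .data$mean_deg)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_deg - .data$sem_deg,
                                      ymax = .data$mean_deg + .data$sem_deg),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle phase", y = "eye position (deg)",
                  subtitle = sprintf("%g Hz, condition %s",
                                     attr(object, "frequency"),
                                     attr(object, "condition"))) +
    ggplot2::theme_minimal()
}

#' Plot a mean evoked movement with its phase boundaries
#'
#' @param mean_profile A mean-trace velocity profile
#'   (`animal_mean_response()$mean`).
#' @param seg Optional [segment_phases()] result to draw phase boundaries.
#' @return A ggplot object (magnitude position and velocity panels).
#' @export
plot_mean_trace <- function(mean_profile, seg = NULL) {
  d <- tidyr::pivot_longer(
    mean_profile[c("rel_time_s", "mag_f_deg", "vel_mag_dps")],
    -"rel_time_s", names_to = "channel"
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time from LED onset (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(c(seg$start_s, seg$end_s)),
                                 linetype = "dotted", color = "grey50")
  }
  p
}
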
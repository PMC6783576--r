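#' Plot the instantaneous-frequency trace of a trial
#'
#' Frequency of every interval against time, with detected chirps (points at
#' their start) and rise spans shaded; the standard diagnostic view of an
#' electromotor-behavior trial.
#'
#' @param report A `trial_report`.
#' @return A ggplot object.
#' @export
plot_frequency_trace <- function(report) {
  stopifnot(inherits(report, "trial_report"))
  iv <- report$intervals
  p <- ggplot2::ggplot(iv, ggplot2::aes(x = .data$t_end, y = .data$freq)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "instantaneous frequency (Hz)")
  if (!is.null(report$rises) && nrow(report$rises)) {
    p <- p + ggplot2::geom_rect(
      data = report$rises, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                   ymin = -Inf, ymax = Inf),
      fill = "orange", alpha = 0.15)
  }
  if (nrow(report$chirps)) {
    p <- p + ggplot2::geom_point(
      data = report$chirps, inherit.aes = FALSE,
      ggplot2::aes(x = .data$start_time, y = .data$peak_freq),
      colour = "red", size = 1.2)
  }
  p
}

#' Phase raster of S1 EODs across the S2 cycle
#'
#' Each subject EOD plotted at its S2 phase against time; the 60-degree
#' windows before and after stimulus coincidence (the critical window) are
#' shaded. Chirp starts, when available, are overplotted.
#'
#' @param train Pulse-train tibble.
#' @param s2 An [s2_schedule()].
#' @param chirps Optional chirp table with `start_time` and `start_phase`.
#' @return A ggplot object.
#' @export
plot_phase_raster <- function(train, s2, chirps = NULL) {
  ph <- compute_phases(train, s2)
  p <- ggplot2::ggplot(ph, ggplot2::aes(x = .data$time, y = .data$phase)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 300, ymax = 360,
                      fill = "green", alpha = 0.12) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0, ymax = 60,
                      fill = "red", alpha = 0.12) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 360),
                                breaks = c(0, 60, 180, 300, 360)) +
    ggplot2::labs(x = "time (s)", y = "phase re S2 (deg)")
  if (!is.null(chirps) && nrow(chirps)) {
    p <- p + ggplot2::geom_point(
      data = chirps[!is.na(chirps$start_phase), ], inherit.aes = FALSE,
      ggplot2::aes(x = .data$start_time, y = .data$start_phase),
      colour = "blue", size = 1.5)
  }
  p
}

#' Plot a jamming profile
#'
#' Jamming index per sliding window, significant windows highlighted.
#'
#' @param profile Output of [jamming_profile()].
#' @return A ggplot object.
#' @export
plot_jamming_profile <- function(profile) {
  mid <- (profile$window_start + profile$window_end) / 2
  df <- dplyr::mutate(profile, t_mid = mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$ji)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "forestgreen")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "window midpoint (s)", y = "jamming index")
}

#' @rdname plot_frequency_trace
#' @param object A `trial_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.trial_report <- function(object, ...) plot_frequency_trace(object)
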
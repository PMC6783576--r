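#' Subtract the S2 stimulus artifact from a recording
#'
#' At each programmed S2 pulse time, the stimulus template is scaled and
#' subtracted, leaving the subject's own EODs. Each pulse's scale is first
#' fitted by least squares over the template support -- robust to the partial
#' attenuation produced by rotating the stimulus electrode away from the
#' recording axis. Because the playback amplitude is constant within a trial,
#' the default `"median"` method subtracts the median fitted scale at every
#' pulse, so the minority of S2 pulses that overlap a subject EOD (whose
#' per-pulse fits are contaminated by the EOD) are still removed cleanly and
#' the coincident EOD's timing is not distorted. `"per_pulse"` subtracts each
#' pulse's own fit. Samples away from S2 pulses are untouched, and the
#' operation is idempotent: refitting on the residual yields a zero scale.
#'
#' @param rec An `eod_recording`.
#' @param s2 An [s2_schedule()] whose `template` is sampled at the recording
#'   rate (falls back to `template` argument).
#' @param template `eod_template` used for the fit when `s2$template` is
#'   `NULL`.
#' @param method Amplitude handling: `"median"` (default) or `"per_pulse"`.
#' @return The cleaned `eod_recording`, with attribute `"fitted_amplitudes"`
#'   holding the per-pulse fitted scales.
#' @export
remove_artifact <- function(rec, s2, template = NULL,
                            method = c("median", "per_pulse")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "eod_recording"), inherits(s2, "s2_schedule"))
  tpl <- s2$template %||% template
  if (is.null(tpl)) stop("an S2 template is required", call. = FALSE)
  if (abs(tpl$sample_rate - rec$sample_rate) > 1e-9) {
    stop("template sample rate does not match the recording", call. = FALSE)
  }
  if (length(s2$times) &&
      (min(s2$times) < 0 || max(s2$times) > rec$duration)) {
    stop("S2 pulse times fall outside the recording span", call. = FALSE)
  }
  x <- rec$samples
  support <- function(j) {
    i0 <- round(s2$times[j] * rec$sample_rate) + 1L
    idx <- i0 - (tpl$peak_index - 1L) + seq_len(tpl$n) - 1L
    idx[idx >= 1L & idx <= length(x)]
  }
  fitted <- vapply(seq_along(s2$times), function(j) {
    idx <- support(j)
    off <- idx - (round(s2$times[j] * rec$sample_rate) + 1L) +
      tpl$peak_index
    sum(x[idx] * tpl$samples[off]) / sum(tpl$samples[off]^2)
  }, numeric(1))
  scale <- if (method == "median" && length(fitted)) {
    rep(median(fitted), length(fitted))
  } else fitted
  for (j in seq_along(s2$times)) {
    idx <- support(j)
    off <- idx - (round(s2$times[j] * rec$sample_rate) + 1L) +
      tpl$peak_index
    x[idx] <- x[idx] - scale[j] * tpl$samples[off]
  }
  out <- new_eod_recording(x, rec$sample_rate)
  attr(out, "fitted_amplitudes") <- fitted
  out
}

#' Detect EOD pulses in a recording
#'
#' Threshold-and-extremum spike detection: samples whose absolute amplitude
#' crosses `threshold` times the recording maximum are grouped into events,
#' groups closer than `refractory` are merged, and the event time is the
#' largest-magnitude extremum of each group. Event amplitude is the
#' peak-to-peak voltage within `+/- amplitude_window` of the event.
#'
#' @param rec An `eod_recording`.
#' @param threshold Detection threshold as a fraction of `max(abs(samples))`,
#'   in (0, 1).
#' @param refractory Minimum separation between events, seconds. The default,
#'   half a typical 2 ms EOD, merges the lobes of one biphasic pulse.
#' @param amplitude_window Half-width of the peak-to-peak measurement window,
#'   seconds; defaults to `refractory * 2`.
#' @return A pulse-train tibble with columns `time` (s) and `amplitude`
#'   (peak-to-peak), ordered by time; empty for an all-zero recording.
#' @export
detect_pulses <- function(rec, threshold = 0.3, refractory = 0.001,
                          amplitude_window = NULL) {
  stopifnot(inherits(rec, "eod_recording"))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  amplitude_window <- amplitude_window %||% (2 * refractory)
  x <- rec$samples
  m <- max(abs(x))
  if (m == 0) return(tibble::tibble(time = double(), amplitude = double()))
  above <- which(abs(x) >= threshold * m)
  if (!length(above)) {
    return(tibble::tibble(time = double(), amplitude = double()))
  }
  gap <- round(refractory * rec$sample_rate)
  grp <- cumsum(c(1L, diff(above) > gap))
  peaks <- vapply(split(above, grp), function(idx) {
    idx[which.max(abs(x[idx]))]
  }, integer(1))
  # merge any surviving peaks still within the refractory period
  if (length(peaks) > 1) {
    keep <- rep(TRUE, length(peaks))
    last <- 1L
    for (i in seq(2L, length(peaks))) {
      if (peaks[i] - peaks[last] <= gap) {
        if (abs(x[peaks[i]]) > abs(x[peaks[last]])) {
          keep[last] <- FALSE; last <- i
        } else keep[i] <- FALSE
      } else last <- i
    }
    peaks <- peaks[keep]
  }
  w <- round(amplitude_window * rec$sample_rate)
  amp <- vapply(peaks, function(p) {
    seg <- x[max(1L, p - w):min(length(x), p + w)]
    max(seg) - min(seg)
  }, numeric(1))
  tibble::tibble(time = (peaks - 1L) / rec$sample_rate, amplitude = amp)
}

#' Build the inter-pulse interval series
#'
#' Converts a detected pulse train into per-interval measures: the IPI, the
#' instantaneous frequency `1 / IPI`, and the percent reduction of each IPI
#' relative to the interval before (rIPI), the statistic used to flag abrupt
#' pacemaker accelerations such as chirps. Positive rIPI means the interval
#' shortened. The first interval has no predecessor, so its rIPI is `NA`.
#'
#' @param train Pulse-train data frame with at least a `time` column
#'   (and optionally `amplitude`), as from [detect_pulses()].
#' @return A tibble with one row per interval: `index`, `t_start`, `t_end`,
#'   `ipi` (s), `freq` (Hz), `ripi` (percent), and `amp_start`/`amp_end` when
#'   amplitudes are available.
#' @examples
#' compute_intervals(tibble::tibble(time = c(0, 0.020, 0.038)))
#' @export
compute_intervals <- function(train) {
  if (nrow(train) < 2) {
    stop("at least 2 pulses are required to form an interval", call. = FALSE)
  }
  t <- train$time
  if (any(diff(t) <= 0)) stop("pulse times must be strictly increasing",
                              call. = FALSE)
  ipi <- diff(t)
  out <- tibble::tibble(
    index = seq_along(ipi),
    t_start = t[-length(t)],
    t_end = t[-1],
    ipi = ipi,
    freq = 1 / ipi,
    ripi = c(NA_real_, 100 * (ipi[-length(ipi)] - ipi[-1]) / ipi[-length(ipi)])
  )
  if ("amplitude" %in% names(train)) {
    out$amp_start <- train$amplitude[-nrow(train)]
    out$amp_end <- train$amplitude[-1]
  }
  out
}

#' Baseline frequency and IPI-variability statistics
#'
#' Summarizes resting discharge over successive windows (the study used about
#' 1 min of intertrial IPI recording per window): mean and standard error of
#' instantaneous frequency, and mean and SD of rIPI. Multiple windows are
#' summarized per window and averaged.
#'
#' @param intervals An interval tibble from [compute_intervals()].
#' @param window Window length in seconds.
#' @return A one-row tibble: `mean_freq`, `freq_se`, `freq_sd`, `mean_ripi`,
#'   `ripi_sd`, `n_intervals`, `n_windows`.
#' @export
baseline_stats <- function(intervals, window = 60) {
  w <- floor((intervals$t_start - intervals$t_start[1]) / window)
  per <- dplyr::group_by(intervals, w = w)
  per <- dplyr::filter(per, dplyr::n() >= 10)
  if (!nrow(per)) {
    stop("no window holds at least 10 intervals", call. = FALSE)
  }
  per <- dplyr::summarise(
    per,
    mean_freq = mean(.data$freq),
    freq_se = sd(.data$freq) / sqrt(dplyr::n()),
    freq_sd = sd(.data$freq),
    mean_ripi = mean(.data$ripi, na.rm = TRUE),
    ripi_sd = sd(.data$ripi, na.rm = TRUE),
    n_intervals = dplyr::n(),
    .groups = "drop"
  )
  tibble::tibble(
    mean_freq = mean(per$mean_freq),
    freq_se = mean(per$freq_se),
    freq_sd = mean(per$freq_sd),
    mean_ripi = mean(per$mean_ripi),
    ripi_sd = mean(per$ripi_sd),
    n_intervals = sum(per$n_intervals),
    n_windows = nrow(per)
  )
}
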
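#' Detect tumultuous rises
#'
#' A tumultuous rise is recognized where two conditions hold together for more
#' than `min_duration`: the coefficient of variation of instantaneous
#' frequency, measured in 200 ms blocks with 50% overlap, exceeds
#' `cv_threshold` percent (reflecting densely interspersed chirp-like
#' intervals), and the running baseline frequency -- a 20-interval moving
#' average -- exceeds the pretest mean by more than `rise_threshold_pct`
#' percent. Event boundaries are then extended outward to where the running
#' baseline re-enters a band of 5 pretest standard deviations around the
#' pretest mean; the same band rule is applied symmetrically at the start.
#'
#' @param intervals Interval tibble from [compute_intervals()].
#' @param pretest One-row baseline tibble from [baseline_stats()] (needs
#'   `mean_freq` and `freq_sd`).
#' @param cv_threshold Block CV threshold, percent.
#' @param rise_threshold_pct Baseline increase threshold, percent.
#' @param min_duration Minimum time both conditions must hold, seconds.
#' @param block Length of the CV blocks, seconds.
#' @param baseline_n Intervals in the running-baseline moving average.
#' @param sd_band Width of the return band in pretest SDs.
#' @return A tibble of rise events with the metrics of [measure_rise()].
#' @export
detect_rises <- function(intervals, pretest, cv_threshold = 5,
                         rise_threshold_pct = 25, min_duration = 0.5,
                         block = 0.2, baseline_n = 20, sd_band = 5) {
  proto <- tibble::tibble(start_time = double(), end_time = double(),
                          duration_s = double(), mean_rise = double(),
                          peak_rise = double(), n_chirp_intervals = integer(),
                          chirp_rate = double())
  t0 <- intervals$t_start[1]
  t1 <- intervals$t_end[nrow(intervals)]
  if (t1 - t0 < block) {
    warning("interval series shorter than one CV block; no rises scored")
    return(proto)
  }
  rb <- running_baseline(intervals, baseline_n)
  starts <- seq(t0, t1 - block, by = block / 2)
  blocks <- purrr::map_dfr(starts, function(s) {
    inb <- intervals$t_start >= s & intervals$t_start < s + block
    f <- intervals$freq[inb]
    cv <- if (length(f) >= 2 && mean(f) > 0) 100 * sd(f) / mean(f) else 0
    base <- mean(rb[inb])
    tibble::tibble(t_mid = s + block / 2, cv = cv, baseline = base)
  })
  cond <- blocks$cv > cv_threshold &
    !is.na(blocks$baseline) &
    blocks$baseline > (1 + rise_threshold_pct / 100) * pretest$mean_freq
  runs <- rle(cond)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  out <- proto
  for (k in which(runs$values)) {
    b0 <- blocks$t_mid[begins[k]] - block / 2
    b1 <- blocks$t_mid[ends[k]] + block / 2
    if (b1 - b0 <= min_duration) next
    band <- sd_band * pretest$freq_sd
    outside <- abs(rb - pretest$mean_freq) > band & !is.na(rb)
    # walk outward while the running baseline stays outside the pretest band
    i0 <- which(intervals$t_start >= b0)[1]
    while (i0 > 1 && isTRUE(outside[i0 - 1])) i0 <- i0 - 1
    i1 <- max(which(intervals$t_end <= b1))
    while (i1 < nrow(intervals) && isTRUE(outside[i1 + 1])) i1 <- i1 + 1
    ev <- measure_rise(intervals, intervals$t_start[i0], intervals$t_end[i1],
                       pretest, baseline_n = baseline_n)
    out <- dplyr::bind_rows(out, ev)
  }
  # merge events whose extension made them contiguous/overlapping
  if (nrow(out) > 1) {
    keep <- c(TRUE, out$start_time[-1] > out$end_time[-nrow(out)])
    if (!all(keep)) {
      merged <- proto
      cur <- out[1, ]
      for (i in seq(2, nrow(out))) {
        if (out$start_time[i] <= cur$end_time) {
          cur <- measure_rise(intervals, cur$start_time, out$end_time[i],
                              pretest, baseline_n = baseline_n)
        } else {
          merged <- dplyr::bind_rows(merged, cur)
          cur <- out[i, ]
        }
      }
      out <- dplyr::bind_rows(merged, cur)
    }
  }
  out
}

# centered moving average of instantaneous frequency over `n` intervals
running_baseline <- function(intervals, n = 20) {
  f <- intervals$freq
  k <- min(n, length(f))
  as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
}

#' Measure a tumultuous rise
#'
#' `mean_rise` is the running-baseline frequency at the temporal midpoint of
#' the rise minus the pretest mean; `peak_rise` the maximum running baseline
#' during the rise minus the pretest mean. Chirp-like intervals inside the
#' rise are counted with the standard 10% rIPI threshold.
#'
#' @param intervals Interval tibble.
#' @param start_time,end_time Rise boundaries, seconds.
#' @param pretest One-row tibble from [baseline_stats()].
#' @param baseline_n Intervals in the running-baseline moving average.
#' @param chirp_threshold_pct rIPI threshold for chirp-like intervals.
#' @return A one-row tibble: `start_time`, `end_time`, `duration_s`,
#'   `mean_rise`, `peak_rise`, `n_chirp_intervals`, `chirp_rate`.
#' @export
measure_rise <- function(intervals, start_time, end_time, pretest,
                         baseline_n = 20, chirp_threshold_pct = 10) {
  rb <- running_baseline(intervals, baseline_n)
  inside <- intervals$t_start >= start_time & intervals$t_end <= end_time
  mid <- (start_time + end_time) / 2
  i_mid <- which.min(abs(intervals$t_start - mid))
  n_chirp <- sum(!is.na(intervals$ripi[inside]) &
                   intervals$ripi[inside] > chirp_threshold_pct)
  dur <- end_time - start_time
  tibble::tibble(
    start_time = start_time, end_time = end_time, duration_s = dur,
    mean_rise = rb[i_mid] - pretest$mean_freq,
    peak_rise = max(rb[inside], na.rm = TRUE) - pretest$mean_freq,
    n_chirp_intervals = n_chirp,
    chirp_rate = n_chirp / dur
  )
}

#' Detect EOD interruptions
#'
#' An interruption spans any inter-pulse gap longer than `gap_factor` times
#' the local median IPI (rolling median over `local_n` intervals). When the
#' recording is supplied, the end of the initial high-frequency hash is
#' located as the last time within the gap at which the short-window RMS of
#' the trace exceeds 3 times the silent-period noise floor (estimated from
#' the final quarter of the gap); without a recording, events are returned
#' with `hash_end_time = NA`.
#'
#' @param train Pulse-train tibble (`time`, `amplitude`).
#' @param rec Optional `eod_recording` for hash-end measurement.
#' @param gap_factor Gap threshold as a multiple of the local median IPI.
#' @param local_n Window (intervals) of the rolling median.
#' @param rms_window RMS window for hash detection, seconds.
#' @return A tibble: `start_time`, `end_time`, `duration_s`,
#'   `hash_end_time`, `local_median_ipi`.
#' @export
detect_interruptions <- function(train, rec = NULL, gap_factor = 2.5,
                                 local_n = 21, rms_window = 0.002) {
  proto <- tibble::tibble(start_time = double(), end_time = double(),
                          duration_s = double(), hash_end_time = double(),
                          local_median_ipi = double())
  if (nrow(train) < 3) return(proto)
  ipi <- diff(train$time)
  med <- rolling_median(ipi, local_n)
  hits <- which(ipi > gap_factor * med)
  if (!length(hits)) return(proto)
  purrr::map_dfr(hits, function(i) {
    start <- train$time[i]
    end <- train$time[i + 1]
    hash_end <- NA_real_
    if (!is.null(rec)) {
      hash_end <- measure_hash_end(rec, start, end, rms_window)
    }
    tibble::tibble(start_time = start, end_time = end,
                   duration_s = end - start, hash_end_time = hash_end,
                   local_median_ipi = med[i])
  })
}

# median over a centered window, excluding the focal value's own gap
rolling_median <- function(x, n = 21) {
  half <- floor(n / 2)
  vapply(seq_along(x), function(i) {
    idx <- setdiff(max(1, i - half):min(length(x), i + half), i)
    median(x[idx])
  }, numeric(1))
}

measure_hash_end <- function(rec, start, end, rms_window = 0.002,
                             edge_guard = 0.003) {
  sr <- rec$sample_rate
  # guard band: keep the deformed onset EOD and the resumption EOD (up to a
  # typical pulse length) out of the analyzed span
  start <- start + edge_guard
  end <- end - edge_guard
  if (end <= start) return(NA_real_)
  i0 <- max(1L, round(start * sr) + 1L)
  i1 <- min(length(rec$samples), round(end * sr))
  if (i1 - i0 < 4) return(NA_real_)
  seg <- rec$samples[i0:i1]
  # noise floor from the last quarter of the gap (the low-noise pause)
  tail_idx <- seq(floor(length(seg) * 0.75), length(seg))
  floor_rms <- sqrt(mean(seg[tail_idx]^2))
  w <- max(2L, round(rms_window * sr))
  n_win <- floor(length(seg) / w)
  if (n_win < 1) return(NA_real_)
  rms <- vapply(seq_len(n_win), function(k) {
    sqrt(mean(seg[((k - 1) * w + 1):(k * w)]^2))
  }, numeric(1))
  hot <- which(rms > 3 * max(floor_rms, .Machine$double.eps))
  if (!length(hot)) return(start)
  start + (max(hot) * w) / sr
}
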
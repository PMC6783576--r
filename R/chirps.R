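#' Detect chirp start indices
#'
#' A chirp start is any interval whose rIPI exceeds `threshold_pct` (10% by
#' default; highly variable species such as *Brachyhypopomus* need 25%) and
#' which is not already inside a previously delimited chirp. Detection and
#' delimitation therefore proceed left to right: once a chirp is delimited,
#' further above-threshold intervals inside it are not new starts.
#'
#' @param intervals An interval tibble from [compute_intervals()].
#' @param threshold_pct rIPI detection threshold, percent (> 0).
#' @return Integer vector of interval indices that start a chirp.
#' @export
detect_chirp_starts <- function(intervals, threshold_pct = 10) {
  if (threshold_pct <= 0) stop("`threshold_pct` must be > 0", call. = FALSE)
  above <- which(!is.na(intervals$ripi) & intervals$ripi > threshold_pct)
  starts <- integer(0)
  claimed_until <- 0L
  for (i in above) {
    if (i <= claimed_until) next
    bounds <- tryCatch(
      delimit_chirp(intervals, i, threshold_pct = threshold_pct),
      error = function(e) NULL)
    if (is.null(bounds)) next   # no local baseline (event at a trial edge)
    starts <- c(starts, i)
    claimed_until <- bounds$last_interval
  }
  starts
}

#' Delimit one chirp
#'
#' Starting from an above-threshold interval, the chirp body is the maximal
#' run of intervals shorter than `(1 - threshold_pct/100)` times the local
#' pre-chirp IPI (mean of the three preceding intervals, or the following
#' three at trial start). The chirp ends when the discharge frequency returns
#' to within 10% of the post-chirp steady-state rate, measured as the mean
#' frequency over `steady_n` intervals beginning at least
#' `post_rate_window` after the last above-threshold interval -- so a chirp
#' followed by a sustained higher plateau (as in *Brachyhypopomus*) is ended
#' against the plateau, not the pre-chirp baseline.
#'
#' @param intervals Interval tibble.
#' @param start_index Index of the first chirp interval.
#' @param threshold_pct rIPI threshold, percent.
#' @param post_rate_window Delay before the steady-state window, seconds.
#' @param steady_n Number of intervals in the steady-state window.
#' @return A list: `start_index`, `last_interval` (last interval belonging to
#'   the chirp), `n_eods`, `start_time`, `end_time`, `truncated` (flag set
#'   when the trial ends before steady state).
#' @export
delimit_chirp <- function(intervals, start_index, threshold_pct = 10,
                          post_rate_window = 0.05, steady_n = 5) {
  n <- nrow(intervals)
  if (start_index < 1 || start_index > n) {
    stop("`start_index` out of range", call. = FALSE)
  }
  base_ipi <- local_baseline(intervals, start_index)$ipi
  short <- intervals$ipi < (1 - threshold_pct / 100) * base_ipi
  last_body <- start_index
  while (last_body < n && short[last_body + 1]) last_body <- last_body + 1
  # steady-state window: >= post_rate_window after the chirp body ends
  t_ref <- intervals$t_end[last_body] + post_rate_window
  cand <- which(intervals$t_start >= t_ref)
  truncated <- length(cand) < steady_n
  steady <- if (truncated) {
    if (length(cand)) mean(intervals$freq[cand])
    else mean(intervals$freq[seq(min(n, last_body + 1), n)])
  } else {
    mean(intervals$freq[cand[seq_len(steady_n)]])
  }
  last_interval <- last_body
  if (last_body < n) {
    after <- seq(last_body + 1, n)
    back <- which(abs(intervals$freq[after] - steady) <= 0.1 * steady)
    if (length(back)) {
      last_interval <- after[back[1]] - 1L
    } else {
      last_interval <- n
      truncated <- TRUE
    }
  } else {
    truncated <- TRUE
  }
  last_interval <- max(last_interval, start_index)
  list(start_index = start_index, last_interval = last_interval,
       n_eods = last_interval - start_index + 2L,
       start_time = intervals$t_start[start_index],
       end_time = intervals$t_end[last_interval],
       truncated = truncated)
}

# 3-interval local baseline before start (after, within the first 5 intervals)
local_baseline <- function(intervals, start_index, n_base = 3) {
  use_after <- start_index <= 5
  idx <- if (use_after) {
    seq(start_index + 1, length.out = n_base)
  } else {
    seq(start_index - n_base, length.out = n_base)
  }
  idx <- idx[idx >= 1 & idx <= nrow(intervals)]
  if (length(idx) < n_base) {
    stop("fewer than ", n_base, " baseline intervals available", call. = FALSE)
  }
  list(
    ipi = mean(intervals$ipi[idx]),
    amplitude = if ("amp_start" %in% names(intervals))
      mean(intervals$amp_start[idx]) else NA_real_,
    side = if (use_after) "after" else "before"
  )
}

#' Measure a delimited chirp
#'
#' Computes the chirp metrics used throughout the analysis: duration in
#' seconds and in S2 cycles, number of EODs, maximum rIPI against the
#' three-EOD local baseline, peak frequency (inverse of the shortest chirp
#' interval), maximum EOD amplitude reduction, times to both maxima, the
#' S2-phase of the chirp's first EOD, and the latency from the first S2 pulse.
#'
#' @param intervals Interval tibble (with amplitude columns for amplitude
#'   metrics).
#' @param chirp A delimitation from [delimit_chirp()].
#' @param s2 Optional [s2_schedule()] supplying the S2 period, first pulse
#'   time and phase reference.
#' @return A one-row tibble of chirp metrics.
#' @export
measure_chirp <- function(intervals, chirp, s2 = NULL) {
  idx <- seq(chirp$start_index, chirp$last_interval)
  base <- local_baseline(intervals, chirp$start_index)
  ipis <- intervals$ipi[idx]
  ripi_vs_base <- 100 * (base$ipi - ipis) / base$ipi
  i_max <- which.max(ripi_vs_base)
  duration_s <- chirp$end_time - chirp$start_time
  have_amp <- "amp_start" %in% names(intervals)
  if (have_amp) {
    eod_amp <- c(intervals$amp_start[idx[1]], intervals$amp_end[idx])
    eod_t <- c(intervals$t_start[idx[1]], intervals$t_end[idx])
    amp_red <- 100 * (1 - eod_amp / base$amplitude)
    j_max <- which.max(amp_red)
  }
  phase <- latency <- duration_cycles <- NA_real_
  if (!is.null(s2)) {
    duration_cycles <- duration_s / s2$period
    first_s2 <- s2$times[1]
    latency <- chirp$start_time - first_s2
    if (chirp$start_time >= first_s2) {
      phase <- 360 * (((chirp$start_time - first_s2) / s2$period) %% 1)
    }
  }
  tibble::tibble(
    start_index = chirp$start_index,
    start_time = chirp$start_time,
    end_time = chirp$end_time,
    n_eods = chirp$n_eods,
    duration_s = duration_s,
    duration_s2_cycles = duration_cycles,
    max_ripi = max(ripi_vs_base),
    time_to_max_ripi = intervals$t_end[idx[i_max]] - chirp$start_time,
    peak_freq = 1 / min(ipis),
    max_amp_reduction = if (have_amp) max(amp_red) else NA_real_,
    time_to_max_amp_reduction = if (have_amp) eod_t[j_max] - chirp$start_time
      else NA_real_,
    start_phase = phase,
    latency_to_first_s2 = latency,
    baseline_side = base$side,
    truncated = chirp$truncated
  )
}

#' Detect and measure all chirps in a trial
#'
#' Convenience wrapper running [detect_chirp_starts()], [delimit_chirp()] and
#' [measure_chirp()] over an interval series, returning the full chirp event
#' table. Chirps are disjoint by construction.
#'
#' @inheritParams detect_chirp_starts
#' @inheritParams measure_chirp
#' @param short_latency_cutoff Latency bound (s) for the short-latency flag;
#'   see [classify_short_latency()].
#' @return A tibble of chirp events (zero rows when none detected).
#' @examples
#' tr <- synth_trial(55, 10, dF = 3, seed = 2, render = FALSE,
#'   events = list(list(type = "chirp", onset_time = 4, ipi_reduction = 40)))
#' iv <- compute_intervals(tr$truth$pulses)
#' detect_chirps(iv, s2 = tr$s2)
#' @export
detect_chirps <- function(intervals, threshold_pct = 10, s2 = NULL,
                          short_latency_cutoff = 0.1) {
  starts <- detect_chirp_starts(intervals, threshold_pct)
  out <- purrr::map_dfr(starts, function(i) {
    ch <- delimit_chirp(intervals, i, threshold_pct = threshold_pct)
    measure_chirp(intervals, ch, s2 = s2)
  })
  if (!nrow(out)) return(chirp_table_prototype())
  classify_short_latency(out, cutoff = short_latency_cutoff)
}

chirp_table_prototype <- function() {
  tibble::tibble(
    start_index = integer(), start_time = double(), end_time = double(),
    n_eods = integer(), duration_s = double(), duration_s2_cycles = double(),
    max_ripi = double(), time_to_max_ripi = double(), peak_freq = double(),
    max_amp_reduction = double(), time_to_max_amp_reduction = double(),
    start_phase = double(), latency_to_first_s2 = double(),
    baseline_side = character(), truncated = logical(),
    short_latency = logical()
  )
}

#' Flag short-latency chirps
#'
#' Chirps beginning strictly less than `cutoff` seconds after the first S2
#' pulse are flagged short-latency; such startle-like chirps (mean latency
#' near 50 ms) are characteristic of *Steatogenys*.
#'
#' @param chirps Chirp table from [detect_chirps()] with a
#'   `latency_to_first_s2` column.
#' @param cutoff Latency cutoff in seconds (strict inequality).
#' @return `chirps` with a logical `short_latency` column.
#' @export
classify_short_latency <- function(chirps, cutoff = 0.1) {
  chirps$short_latency <- !is.na(chirps$latency_to_first_s2) &
    chirps$latency_to_first_s2 >= 0 & chirps$latency_to_first_s2 < cutoff
  chirps
}

#' Detect burst-like chirping episodes
#'
#' Chirp-like intervals (rIPI above threshold) repeated with at most
#' `max_normal_gap` normal intervals between them are merged into episodes
#' ("fewer than three normal intervals" in the defining description, hence
#' the default gap of 2). An episode must contain at least two chirp-like
#' intervals.
#'
#' @param intervals Interval tibble.
#' @param chirp_like Optional integer indices of chirp-like intervals;
#'   computed from `threshold_pct` when omitted.
#' @param threshold_pct rIPI threshold for chirp-like intervals, percent.
#' @param max_normal_gap Maximum run of normal intervals inside an episode.
#' @return A tibble of episodes: `start_time`, `end_time`, `duration_s`,
#'   `n_chirp_intervals`, `chirps_per_second`.
#' @export
detect_burst_episodes <- function(intervals, chirp_like = NULL,
                                  threshold_pct = 10, max_normal_gap = 2) {
  if (is.null(chirp_like)) {
    chirp_like <- which(!is.na(intervals$ripi) &
                          intervals$ripi > threshold_pct)
  }
  proto <- tibble::tibble(start_time = double(), end_time = double(),
                          duration_s = double(), n_chirp_intervals = integer(),
                          chirps_per_second = double())
  if (length(chirp_like) < 2) return(proto)
  grp <- cumsum(c(1L, diff(chirp_like) > max_normal_gap + 1L))
  purrr::map_dfr(split(chirp_like, grp), function(idx) {
    if (length(idx) < 2) return(NULL)
    start <- intervals$t_start[idx[1]]
    end <- intervals$t_end[idx[length(idx)]]
    tibble::tibble(start_time = start, end_time = end,
                   duration_s = end - start,
                   n_chirp_intervals = length(idx),
                   chirps_per_second = length(idx) / (end - start))
  })
}
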
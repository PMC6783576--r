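#' @noRd
new_eod_truth <- function(pulses, events, baseline_frequency, jitter_cv,
                          trial_duration, seed = NULL) {
  structure(
    list(pulses = pulses, events = events,
         baseline_frequency = baseline_frequency, jitter_cv = jitter_cv,
         trial_duration = trial_duration, seed = seed),
    class = "eod_truth"
  )
}

empty_events <- function() {
  tibble::tibble(event_id = integer(), type = character(),
                 start_time = double(), end_time = double(),
                 n_intervals = integer(), detail = list())
}

add_event <- function(truth, type, start_time, end_time, n_intervals, detail) {
  ev <- tibble::tibble(event_id = nrow(truth$events) + 1L, type = type,
                       start_time = start_time, end_time = end_time,
                       n_intervals = as.integer(n_intervals),
                       detail = list(detail))
  truth$events <- dplyr::bind_rows(truth$events, ev)
  truth
}

check_overlap <- function(truth, start, end) {
  ev <- truth$events
  if (nrow(ev) && any(ev$start_time < end & ev$end_time > start)) {
    stop("injected events may not overlap", call. = FALSE)
  }
  invisible(NULL)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' @export
print.eod_truth <- function(x, ...) {
  cat(sprintf("<eod_truth> %d pulses over %.1f s (baseline %.1f Hz, jitter CV %.4f)\n",
              nrow(x$pulses), x$trial_duration, x$baseline_frequency, x$jitter_cv))
  if (nrow(x$events)) {
    cat("events:", paste(sprintf("%s [%.2f-%.2f s]", x$events$type,
                                 x$events$start_time, x$events$end_time),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eod_truth <- function(x, ...) x$pulses

draw_ipis <- function(n, mean_ipi, cv) {
  if (cv == 0) return(rep(mean_ipi, n))
  ipi <- rnorm(n, mean_ipi, cv * mean_ipi)
  bad <- ipi < 0.2 * mean_ipi
  while (any(bad)) {
    ipi[bad] <- rnorm(sum(bad), mean_ipi, cv * mean_ipi)
    bad <- ipi < 0.2 * mean_ipi
  }
  ipi
}

#' Generate a ground-truthed baseline EOD pulse train
#'
#' Draws a regular pulse train at a given baseline discharge frequency with
#' independent Gaussian inter-pulse-interval (IPI) jitter, truncated at 0.2 of
#' the mean IPI so intervals stay positive. Pulse gymnotiform baselines are
#' highly regular (IPI coefficients of variation well below 1%), so
#' `jitter_cv` values above 0.5 are rejected as unrealistic. The first pulse
#' falls at a uniform random phase offset within one period.
#'
#' @param frequency Baseline EOD rate in Hz (> 0).
#' @param duration Trial duration in seconds (> 0).
#' @param jitter_cv Coefficient of variation of the IPIs (0 <= cv < 0.5).
#' @param seed Optional integer seed; a fixed seed makes the train
#'   bit-reproducible.
#' @return An `eod_truth` object: `pulses` (tibble of `time`, `amplitude`),
#'   `events` (empty tibble, filled by the `inject_*` functions), and the
#'   generating parameters.
#' @examples
#' tr <- synth_baseline_train(50, 1, jitter_cv = 0, seed = 1)
#' nrow(tr$pulses)
#' @seealso [inject_chirp()], [inject_tumultuous_rise()],
#'   [inject_interruption()], [render_waveform()]
#' @export
synth_baseline_train <- function(frequency, duration, jitter_cv = 0.002,
                                 seed = NULL) {
  if (!is.numeric(frequency) || length(frequency) != 1 || frequency <= 0) {
    stop("`frequency` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (jitter_cv < 0 || jitter_cv >= 0.5) {
    stop("`jitter_cv` must lie in [0, 0.5)", call. = FALSE)
  }
  mean_ipi <- 1 / frequency
  times <- with_seed_if(seed, {
    t0 <- runif(1, 0, mean_ipi)
    n_max <- ceiling(duration * frequency * (1 + 6 * jitter_cv)) + 8L
    tt <- t0 + cumsum(c(0, draw_ipis(n_max, mean_ipi, jitter_cv)))
    tt[tt < duration]
  })
  pulses <- tibble::tibble(time = times, amplitude = rep(1, length(times)))
  new_eod_truth(pulses, empty_events(), frequency, jitter_cv, duration, seed)
}

#' Inject a chirp into a ground-truth pulse train
#'
#' Shortens `length(ipi_reduction)` consecutive intervals, each expressed as a
#' percent reduction of the pre-chirp IPI (the interval immediately before
#' `onset_index`), and scales down the amplitudes of the chirp EODs. All later
#' pulse times shift earlier by the total time removed, mimicking a transient
#' pacemaker acceleration. The event is recorded in the ground truth.
#'
#' @param truth An `eod_truth` object.
#' @param onset_index Index (into `truth$pulses`) of the first chirp EOD;
#'   must be >= 2 and leave room for the profile.
#' @param ipi_reduction Percent reduction per chirp interval, each in
#'   \[0, 95\]; length `n_eods - 1`.
#' @param amp_reduction Percent amplitude reduction per chirp EOD, length
#'   `n_eods`; defaults to no reduction.
#' @return The modified `eod_truth`.
#' @examples
#' tr <- synth_baseline_train(50, 2, jitter_cv = 0, seed = 1)
#' tr <- inject_chirp(tr, 20, ipi_reduction = 44.1)
#' tr$events
#' @export
inject_chirp <- function(truth, onset_index, ipi_reduction,
                         amp_reduction = NULL) {
  stopifnot(inherits(truth, "eod_truth"))
  m <- length(ipi_reduction)
  n_eods <- m + 1L
  if (is.null(amp_reduction)) amp_reduction <- rep(0, n_eods)
  if (length(amp_reduction) != n_eods) {
    stop("`amp_reduction` must have length `length(ipi_reduction) + 1`",
         call. = FALSE)
  }
  if (any(ipi_reduction < 0 | ipi_reduction > 95) ||
      any(amp_reduction < 0 | amp_reduction > 95)) {
    stop("reductions must lie in [0, 95] percent", call. = FALSE)
  }
  t <- truth$pulses$time
  n <- length(t)
  if (onset_index < 2 || onset_index + m > n) {
    stop("`onset_index` out of range for this profile", call. = FALSE)
  }
  pre_ipi <- t[onset_index] - t[onset_index - 1]
  new_ipi <- pre_ipi * (1 - ipi_reduction / 100)
  idx <- onset_index + seq_len(m)          # pulses moved within the chirp
  old_tail_start <- t[onset_index + m]
  t[idx] <- t[onset_index] + cumsum(new_ipi)
  shift <- old_tail_start - t[onset_index + m]
  if (onset_index + m < n) {
    later <- seq(onset_index + m + 1L, n)
    t[later] <- t[later] - shift
  }
  amp <- truth$pulses$amplitude
  eods <- onset_index + 0:m
  amp[eods] <- amp[eods] * (1 - amp_reduction / 100)
  check_overlap(truth, t[onset_index], t[onset_index + m])
  truth$pulses$time <- t
  truth$pulses$amplitude <- amp
  add_event(truth, "chirp", t[onset_index], t[onset_index + m], m,
            list(onset_index = onset_index, n_eods = n_eods,
                 ipi = new_ipi, ipi_reduction = ipi_reduction,
                 amp_reduction = amp_reduction))
}

# trapezoidal 0-1 ramp: rise over the first `edge` fraction, fall over the last
ramp01 <- function(x, edge = 0.15) {
  pmax(0, pmin(1, pmin(x / edge, (1 - x) / edge)))
}

#' Inject a tumultuous rise
#'
#' Replaces the pulse train within `[start, start + duration]` with a train
#' whose instantaneous frequency follows a piecewise-linear up/plateau/down
#' ramp of height `rise_hz` above the baseline, with chirp-like shortened
#' intervals interspersed at `chirp_rate` events per second. The pulse train
#' after the rise resumes the baseline rate. This emulates the tumultuous
#' rise: a sustained (> 500 ms) large frequency increase densely packed with
#' chirp-like intervals.
#'
#' @param truth An `eod_truth` object.
#' @param start,duration Rise onset time and length in seconds;
#'   `duration >= 0.5` so the event is long enough to be detectable.
#' @param rise_hz Plateau height above baseline, Hz (> 0).
#' @param chirp_rate Chirp-like intervals per second within the rise.
#' @param chirp_reduction Percent IPI reduction of each chirp-like interval.
#' @param edge_fraction Fraction of `duration` spent on each linear ramp edge.
#' @return The modified `eod_truth`.
#' @export
inject_tumultuous_rise <- function(truth, start, duration, rise_hz,
                                   chirp_rate = 15.61, chirp_reduction = 35,
                                   edge_fraction = 0.15) {
  stopifnot(inherits(truth, "eod_truth"))
  if (duration < 0.5) stop("`duration` must be >= 0.5 s", call. = FALSE)
  if (rise_hz <= 0) stop("`rise_hz` must be > 0", call. = FALSE)
  end <- start + duration
  check_overlap(truth, start, end)
  f0 <- truth$baseline_frequency
  cv <- truth$jitter_cv
  keep <- truth$pulses$time < start
  if (!any(keep)) stop("rise must start after the first pulse", call. = FALSE)
  t_pre <- truth$pulses$time[keep]
  amp_pre <- truth$pulses$amplitude[keep]

  n_chirps <- floor(chirp_rate * duration)
  chirp_times <- if (n_chirps > 0) start + (seq_len(n_chirps) - 0.5) / chirp_rate
                 else numeric(0)
  t_cur <- t_pre[length(t_pre)]
  new_t <- numeric(0)
  chirp_flag <- logical(0)
  next_chirp <- 1L
  repeat {
    x <- (t_cur - start) / duration
    f <- f0 + rise_hz * ramp01(min(max(x, 0), 1), edge_fraction)
    ipi <- draw_ipis(1L, 1 / f, cv)
    is_chirp <- next_chirp <= n_chirps && t_cur + ipi > chirp_times[next_chirp]
    if (is_chirp) {
      ipi <- ipi * (1 - chirp_reduction / 100)
      next_chirp <- next_chirp + 1L
    }
    t_cur <- t_cur + ipi
    if (t_cur >= end) break
    new_t <- c(new_t, t_cur)
    chirp_flag <- c(chirp_flag, is_chirp)
  }
  # resume baseline after the rise; t_cur (the pulse that crossed the rise
  # end) is the first post-rise pulse
  tail_t <- numeric(0)
  while (t_cur < truth$trial_duration) {
    tail_t <- c(tail_t, t_cur)
    t_cur <- t_cur + draw_ipis(1L, 1 / f0, cv)
  }
  times <- c(t_pre, new_t, tail_t)
  pulses <- tibble::tibble(
    time = times,
    amplitude = c(amp_pre, rep(1, length(new_t) + length(tail_t)))
  )
  truth$pulses <- pulses
  add_event(truth, "rise", start, end, length(new_t),
            list(rise_hz = rise_hz, chirp_rate = chirp_rate,
                 chirp_reduction = chirp_reduction,
                 n_chirp_intervals = sum(chirp_flag),
                 chirp_times = new_t[chirp_flag]))
}

#' Inject an EOD interruption ("hushing silence")
#'
#' Removes all pulses within `(start, start + duration)`. Following the
#' structure of recorded interruptions, the last pulse before the silence is
#' re-timed to `start` (producing the very shortened IPI that begins the
#' interruption) and its amplitude greatly reduced; the resuming train is
#' shifted so discharge restarts exactly at `start + duration`. The initial
#' `hash_fraction` of the silence is marked as a high-frequency hash span,
#' rendered as band-limited noise by [render_waveform()].
#'
#' @param truth An `eod_truth` object.
#' @param start,duration Silence onset and length in seconds (`duration > 0`;
#'   recorded interruptions span roughly 0.04-0.09 s).
#' @param hash_fraction Fraction of the silence occupied by hash noise.
#' @param deformed_amplitude Amplitude scale of the deformed EOD at onset.
#' @return The modified `eod_truth`.
#' @export
inject_interruption <- function(truth, start, duration, hash_fraction = 0.5,
                                deformed_amplitude = 0.3) {
  stopifnot(inherits(truth, "eod_truth"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (hash_fraction < 0 || hash_fraction > 1) {
    stop("`hash_fraction` must lie in [0, 1]", call. = FALSE)
  }
  end <- start + duration
  check_overlap(truth, start, end)
  t <- truth$pulses$time
  amp <- truth$pulses$amplitude
  i_pre <- which(t < start)
  i_post <- which(t >= end)
  if (!length(i_pre) || !length(i_post)) {
    stop("interruption must fall inside the pulse train", call. = FALSE)
  }
  removed <- which(t >= start & t < end)
  last_pre <- max(i_pre)
  t[last_pre] <- start                  # shortened IPI into the silence
  amp[last_pre] <- amp[last_pre] * deformed_amplitude
  shift <- t[min(i_post)] - end
  t[i_post] <- t[i_post] - shift        # abrupt return exactly at `end`
  keep <- setdiff(seq_along(t), removed)
  truth$pulses <- tibble::tibble(time = t[keep], amplitude = amp[keep])
  add_event(truth, "interruption", start, end, 0L,
            list(hash_end = start + hash_fraction * duration,
                 hash_fraction = hash_fraction,
                 n_removed = length(removed)))
}

#' Build a fixed-period synthetic conspecific (S2) schedule
#'
#' The playback stimulus is a pulse train at a fixed period
#' `1 / (s1_baseline + dF)`, where `dF` is the initial frequency difference
#' between the stimulus and the subject's baseline rate (the study protocol
#' used dF from -16 to +16 Hz and 10 or 15 s trials).
#'
#' @param s1_baseline Subject baseline frequency, Hz.
#' @param dF Initial S2 - S1 frequency difference, Hz; `s1_baseline + dF`
#'   must be positive.
#' @param trial_duration Trial length in seconds.
#' @param phase_offset First-pulse offset as a fraction of the S2 period.
#' @param amplitude S2 amplitude as a fraction of the subject's EOD peak
#'   (calibrated to 0.8-1.0 in the playback protocol).
#' @param template Optional `eod_template` used when rendering.
#' @return An `s2_schedule`: list with `times`, `period`, `amplitude`,
#'   `template`.
#' @examples
#' s2 <- s2_schedule(50, 2, 10)
#' length(s2$times); s2$period
#' @export
s2_schedule <- function(s1_baseline, dF, trial_duration, phase_offset = 0,
                        amplitude = 0.9, template = NULL) {
  f2 <- s1_baseline + dF
  if (f2 <= 0) stop("S2 frequency `s1_baseline + dF` must be > 0", call. = FALSE)
  if (phase_offset < 0 || phase_offset >= 1) {
    stop("`phase_offset` must lie in [0, 1)", call. = FALSE)
  }
  period <- 1 / f2
  # half-open [0, trial_duration): a pulse landing exactly at the trial end
  # is excluded (direct multiplication avoids seq() endpoint fuzz)
  k_max <- ceiling(trial_duration / period) + 1L
  times <- (phase_offset + 0:k_max) * period
  times <- times[times < trial_duration - 1e-12]
  structure(list(times = times, period = period, amplitude = amplitude,
                 template = template),
            class = "s2_schedule")
}

#' @export
print.s2_schedule <- function(x, ...) {
  cat(sprintf("<s2_schedule> %d pulses, period %.4f ms, amplitude %.2f\n",
              length(x$times), 1000 * x$period, x$amplitude))
  invisible(x)
}
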
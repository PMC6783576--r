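#' Phase angles of S1 EODs relative to the S2 cycle
#'
#' Each subject EOD occurring after the first stimulus pulse is assigned a
#' phase angle `360 * (t - t_prevS2) / T_S2`, wrapped to `[0, 360)`, where
#' `t_prevS2` is the preceding S2 pulse time and `T_S2` the fixed stimulus
#' period. EODs before the first S2 are excluded; their count is recorded in
#' the `"n_skipped"` attribute.
#'
#' @param train Pulse-train tibble (`time`, optionally `amplitude`).
#' @param s2 An [s2_schedule()].
#' @return A tibble: `time`, `phase` (degrees in `[0, 360)`),
#'   `s2_cycle` (index of the preceding S2 pulse).
#' @examples
#' s2 <- s2_schedule(50, 0, 1)
#' compute_phases(tibble::tibble(time = c(0.01, 0.03)), s2)
#' @export
compute_phases <- function(train, s2) {
  stopifnot(inherits(s2, "s2_schedule"))
  t <- train$time
  keep <- t >= s2$times[1]
  tt <- t[keep]
  cyc <- findInterval(tt, s2$times)
  # fixed-period schedule: phase by modulo arithmetic from the first S2
  phase <- 360 * (((tt - s2$times[1]) / s2$period) %% 1)
  phase[phase >= 360] <- 0
  out <- tibble::tibble(time = tt, phase = phase, s2_cycle = cyc)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Width of a phase window in seconds
#'
#' Converts a phase window (degrees of the discharge cycle) to time at a given
#' discharge frequency: for a 50 Hz fish the 120-degree critical window
#' surrounding coincidence spans 6.7 ms.
#'
#' @param frequency Discharge frequency in Hz (> 0).
#' @param window_deg Window width in degrees.
#' @return Window width in seconds.
#' @examples
#' critical_window_ms(50) * 1000   # 6.7 ms
#' @export
critical_window_ms <- function(frequency, window_deg = 120) {
  if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  (window_deg / 360) / frequency
}

#' The jamming index of a set of phase angles
#'
#' Within the 120-degree critical window around stimulus coincidence, the
#' index is the proportion of S1 EODs in the 60 degrees before the S2 (phase
#' in `[300, 360)`) minus the proportion in the 60 degrees after (phase in
#' `[0, 60)`), using the total count within the critical window as the
#' denominator. It ranges from -1 (all critical-window S1s follow the S2:
#' S1 is being jammed) to +1 (all precede it: S1 is jamming the S2), with 0
#' an even split. Angles outside the critical window do not enter.
#'
#' @param phases Phase angles in degrees, `[0, 360)`.
#' @return A list: `ji` (`NA` when no phase falls in the critical window),
#'   `n_prior`, `n_after`, `n_critical`.
#' @examples
#' jamming_index(c(10, 25, 40, 55))$ji    # -1
#' jamming_index(c(305, 320, 340, 355))$ji # +1
#' @export
jamming_index <- function(phases) {
  n_prior <- sum(phases >= 300 & phases < 360)
  n_after <- sum(phases >= 0 & phases < 60)
  n_critical <- n_prior + n_after
  ji <- if (n_critical == 0) NA_real_ else (n_prior - n_after) / n_critical
  list(ji = ji, n_prior = n_prior, n_after = n_after,
       n_critical = n_critical)
}

#' Permutation-null standard deviation of the jamming index
#'
#' Simulates `reps` windows of `n` phase angles drawn uniformly on
#' `[0, 360)` and returns the standard deviation of their jamming indices.
#' Draws in which no angle lands in the critical window (undefined index) are
#' redrawn. This null depends only on `n`, the number of S1 pulses in the
#' window.
#'
#' @param n Number of S1 pulses in the window (>= 1).
#' @param reps Number of shuffled windows.
#' @param seed Optional seed.
#' @return Standard deviation of the shuffled jamming indices.
#' @export
jamming_null_sd <- function(n, reps = 10000, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  with_seed_if(seed, {
    ph <- matrix(runif(reps * n, 0, 360), nrow = reps)
    p <- rowSums(ph >= 300)
    a <- rowSums(ph < 60)
    k <- p + a
    bad <- which(k == 0)
    while (length(bad)) {
      ph2 <- matrix(runif(length(bad) * n, 0, 360), nrow = length(bad))
      p[bad] <- rowSums(ph2 >= 300)
      a[bad] <- rowSums(ph2 < 60)
      k[bad] <- p[bad] + a[bad]
      bad <- bad[k[bad] == 0]
    }
    sd((p - a) / k)
  })
}

#' Z-score a jamming index against its permutation null
#'
#' The measured index is divided by the standard deviation of
#' [jamming_null_sd()]'s 10000 uniform shuffles for the same number of S1
#' pulses; indices with `|z| > 1.96` are flagged significant (the sign gives
#' the jamming direction).
#'
#' @param ji Measured jamming index (may be `NA`).
#' @param n_s1_in_window Number of S1 pulses in the window.
#' @param reps Shuffles for the null.
#' @param seed Optional seed.
#' @param null_sd Optional precomputed null SD (overrides simulation).
#' @return A list: `z`, `significant`, `null_sd`.
#' @export
jamming_null_z <- function(ji, n_s1_in_window, reps = 10000, seed = NULL,
                           null_sd = NULL) {
  if (is.na(ji) || n_s1_in_window < 1) {
    return(list(z = NA_real_, significant = FALSE, null_sd = NA_real_))
  }
  s <- null_sd %||% jamming_null_sd(n_s1_in_window, reps, seed)
  z <- ji / s
  list(z = z, significant = abs(z) > 1.96, null_sd = s)
}

#' Sliding-window jamming profile of a trial
#'
#' Tiles the trial with measurement windows (400 ms, 50% overlap by default)
#' anchored at the trial start; each window carries its jamming index,
#' permutation z-score and significance flag. A final partial window, when
#' the trial length is not a multiple of the step, is reported and flagged
#' `partial`. One permutation null is simulated per distinct pulse count,
#' since the null depends only on that count.
#'
#' @param train Pulse-train tibble.
#' @param s2 An [s2_schedule()].
#' @param window Window length, seconds.
#' @param overlap Fractional overlap between successive windows.
#' @param reps Shuffles per permutation null.
#' @param seed Seed for the permutation nulls.
#' @param trial_duration Trial length; defaults to the last event time.
#' @return A tibble with one row per window: `window_start`, `window_end`,
#'   `n_s1`, `n_prior`, `n_after`, `n_critical`, `ji`, `z`, `significant`,
#'   `partial`.
#' @export
jamming_profile <- function(train, s2, window = 0.4, overlap = 0.5,
                            reps = 10000, seed = NULL,
                            trial_duration = NULL) {
  phases <- compute_phases(train, s2)
  dur <- trial_duration %||% max(train$time, s2$times)
  step <- window * (1 - overlap)
  starts <- seq(0, dur, by = step)
  starts <- starts[starts + window <= dur + 1e-9]
  partial_start <- NULL
  covered <- if (length(starts)) starts[length(starts)] + window else 0
  if (covered < dur - 1e-9) {
    partial_start <- if (length(starts)) starts[length(starts)] + step else 0
  }
  all_starts <- c(starts, partial_start)
  is_partial <- c(rep(FALSE, length(starts)), !is.null(partial_start))
  counts <- purrr::map_int(all_starts, function(s) {
    sum(phases$time >= s & phases$time < min(s + window, dur))
  })
  null_sds <- new.env(parent = emptyenv())
  seed_base <- if (is.null(seed)) NULL else as.integer(seed)
  for (n in sort(unique(counts[counts > 0]))) {
    s_n <- if (is.null(seed_base)) NULL else seed_base + n
    assign(as.character(n), jamming_null_sd(n, reps, seed = s_n),
           envir = null_sds)
  }
  purrr::map2_dfr(all_starts, seq_along(all_starts), function(s, i) {
    e <- min(s + window, dur)
    ph <- phases$phase[phases$time >= s & phases$time < e]
    jx <- jamming_index(ph)
    zres <- if (length(ph)) {
      jamming_null_z(jx$ji, length(ph),
                     null_sd = get(as.character(length(ph)), envir = null_sds))
    } else list(z = NA_real_, significant = FALSE)
    tibble::tibble(window_start = s, window_end = e, n_s1 = length(ph),
                   n_prior = jx$n_prior, n_after = jx$n_after,
                   n_critical = jx$n_critical, ji = jx$ji, z = zres$z,
                   significant = zres$significant, partial = is_partial[i])
  })
}

#' Summarize contiguous significant jamming spans
#'
#' Merges runs of significant windows of the same sign into spans with onset,
#' duration and direction (+1: S1 jamming the S2; -1: S1 being jammed).
#'
#' @param profile Output of [jamming_profile()].
#' @return A tibble: `onset`, `end`, `duration_s`, `sign`, `n_windows`.
#' @export
summarize_jamming <- function(profile) {
  proto <- tibble::tibble(onset = double(), end = double(),
                          duration_s = double(), sign = double(),
                          n_windows = integer())
  sig <- profile$significant & !is.na(profile$ji)
  if (!any(sig)) return(proto)
  s <- ifelse(sig, sign(profile$ji), 0)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  purrr::map_dfr(which(runs$values != 0), function(k) {
    tibble::tibble(onset = profile$window_start[begins[k]],
                   end = profile$window_end[ends[k]],
                   duration_s = profile$window_end[ends[k]] -
                     profile$window_start[begins[k]],
                   sign = runs$values[k],
                   n_windows = runs$lengths[k])
  })
}
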
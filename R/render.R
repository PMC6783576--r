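# add `template$samples * scale` to `samples`, template peak aligned at time t
add_pulse_at <- function(samples, t, template, scale, sample_rate) {
  i0 <- round(t * sample_rate) + 1L
  idx <- i0 - (template$peak_index - 1L) + seq_len(template$n) - 1L
  ok <- idx >= 1L & idx <= length(samples)
  samples[idx[ok]] <- samples[idx[ok]] + scale * template$samples[ok]
  samples
}

#' Render a synthetic recording from ground truth
#'
#' Produces the single-channel voltage trace a recording electrode would see:
#' the sum of the subject's (S1) EOD pulses (template scaled by each pulse
#' amplitude), the playback stimulus (S2) pulses at their fixed period and
#' calibrated amplitude, band-limited hash noise within interruption hash
#' spans, and Gaussian sensor noise. The template's largest-magnitude extremum
#' is aligned to each scheduled pulse time, so detected extremum times match
#' ground-truth times to within one sample.
#'
#' @param truth An `eod_truth` object.
#' @param template An [eod_template()] sampled at `sample_rate`.
#' @param s2 Optional [s2_schedule()]; its pulses are added at
#'   `s2$amplitude` relative to the S1 peak.
#' @param sample_rate Sampling rate in Hz (study hardware: 48828.125 Hz).
#' @param noise_sd Gaussian sensor noise standard deviation (amplitude units).
#' @param hash_amplitude RMS of interruption hash noise relative to EOD peak.
#' @param seed Optional seed controlling the noise draw.
#' @return An `eod_recording`: list with `samples`, `sample_rate`, `duration`.
#' @export
render_waveform <- function(truth, template, s2 = NULL,
                            sample_rate = template$sample_rate,
                            noise_sd = 0, hash_amplitude = 0.1, seed = NULL) {
  stopifnot(inherits(truth, "eod_truth"), inherits(template, "eod_template"))
  if (abs(template$sample_rate - sample_rate) > 1e-9) {
    stop("template must be sampled at `sample_rate`", call. = FALSE)
  }
  n <- round(truth$trial_duration * sample_rate)
  x <- numeric(n)
  for (i in seq_len(nrow(truth$pulses))) {
    x <- add_pulse_at(x, truth$pulses$time[i], template,
                      truth$pulses$amplitude[i], sample_rate)
  }
  if (!is.null(s2)) {
    tpl2 <- s2$template %||% template
    for (t in s2$times) {
      x <- add_pulse_at(x, t, tpl2, s2$amplitude, sample_rate)
    }
  }
  x <- with_seed_if(seed, {
    ints <- truth$events[truth$events$type == "interruption", ]
    if (nrow(ints)) {
      for (i in seq_len(nrow(ints))) {
        h0 <- ints$start_time[i]
        h1 <- ints$detail[[i]]$hash_end
        idx <- seq(max(1L, round(h0 * sample_rate) + 1L),
                   min(n, round(h1 * sample_rate)))
        if (length(idx) > 1) {
          # first-differenced white noise: high-pass "hash", peak-scaled so
          # the hash stays well below the pulse-detection threshold
          w <- rnorm(length(idx) + 1)
          hp <- diff(w)
          x[idx] <- x[idx] + hash_amplitude * hp / max(abs(hp))
        }
      }
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    x
  })
  new_eod_recording(x, sample_rate)
}

new_eod_recording <- function(samples, sample_rate) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "eod_recording")
}

#' @export
print.eod_recording <- function(x, ...) {
  cat(sprintf("<eod_recording> %.2f s @ %.3f Hz (%d samples)\n",
              x$duration, x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Generate a complete synthetic playback trial
#'
#' One-stop generator tying the synthetic stages together: a jittered baseline
#' train, injected events, a fixed-period S2 schedule, and (optionally) the
#' rendered voltage trace. Defaults follow the playback protocol: baselines in
#' the 20-90 Hz range, dF within +/-16 Hz, S2 amplitude 80-100% of the
#' subject's peak, 10 or 15 s trials.
#'
#' @param baseline_frequency Subject baseline EOD rate, Hz.
#' @param trial_duration Trial length, seconds.
#' @param jitter_cv IPI coefficient of variation.
#' @param dF Initial S2 - S1 frequency difference, Hz (within +/-16).
#' @param s2_amplitude_ratio S2 amplitude as a fraction of the S1 peak.
#' @param noise_sd Gaussian sensor-noise SD for the rendering.
#' @param events List of event specifications, each a list with `type`
#'   (`"chirp"`, `"rise"` or `"interruption"`) plus the arguments of the
#'   corresponding `inject_*` function (`onset_time` replaces `onset_index`
#'   for chirps).
#' @param sample_rate Rendering sample rate, Hz.
#' @param template_duration EOD template duration, seconds.
#' @param render If `FALSE`, skip waveform rendering (ground truth only).
#' @param seed Integer seed; fixed seed gives a bit-identical trial.
#' @return A list with `truth`, `s2`, `template`, `recording` (or `NULL`),
#'   and `params`.
#' @examples
#' trial <- synth_trial(55, 10, dF = 4, seed = 1, render = FALSE,
#'   events = list(list(type = "chirp", onset_time = 3, ipi_reduction = 40)))
#' trial$truth$events
#' @export
synth_trial <- function(baseline_frequency = 55, trial_duration = 10,
                        jitter_cv = 0.002, dF = 4, s2_amplitude_ratio = 0.9,
                        noise_sd = 0, events = list(),
                        sample_rate = 48828.125, template_duration = 0.002,
                        render = TRUE, seed = NULL) {
  if (abs(dF) > 16) {
    warning("`dF` outside the +/-16 Hz playback protocol range")
  }
  seed <- if (is.null(seed)) NULL else as.integer(seed)
  with_seed_if(seed, {
    truth <- synth_baseline_train(baseline_frequency, trial_duration,
                                  jitter_cv, seed = NULL)
    for (ev in events) {
      type <- ev$type
      if (type == "chirp") {
        onset_index <- if (!is.null(ev$onset_index)) ev$onset_index
          else which(truth$pulses$time >= ev$onset_time)[1]
        truth <- inject_chirp(truth, onset_index, ev$ipi_reduction,
                              ev$amp_reduction)
      } else if (type == "rise") {
        truth <- inject_tumultuous_rise(
          truth, ev$start, ev$duration, ev$rise_hz,
          chirp_rate = ev$chirp_rate %||% 15.61,
          chirp_reduction = ev$chirp_reduction %||% 35)
      } else if (type == "interruption") {
        truth <- inject_interruption(truth, ev$start, ev$duration,
                                     hash_fraction = ev$hash_fraction %||% 0.5)
      } else {
        stop("unknown event type: ", type, call. = FALSE)
      }
    }
    template <- eod_template(template_duration, sample_rate)
    s2 <- s2_schedule(baseline_frequency, dF, trial_duration,
                      phase_offset = runif(1), amplitude = s2_amplitude_ratio,
                      template = template)
    rec <- if (render) {
      render_waveform(truth, template, s2, sample_rate, noise_sd = noise_sd,
                      seed = NULL)
    }
    list(truth = truth, s2 = s2, template = template, recording = rec,
         params = list(baseline_frequency = baseline_frequency,
                       trial_duration = trial_duration, jitter_cv = jitter_cv,
                       dF = dF, s2_amplitude_ratio = s2_amplitude_ratio,
                       noise_sd = noise_sd, sample_rate = sample_rate,
                       seed = seed))
  })
}
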
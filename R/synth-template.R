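#' Build a normalized EOD pulse template
#'
#' Constructs a short biphasic or triphasic pulse waveform resembling a single
#' electric organ discharge (EOD) of a pulse-type gymnotiform. The waveform is
#' zero-mean, smoothly windowed to zero at both ends (Hann taper), and
#' normalized so its largest absolute amplitude equals 1. Pulse-type EODs are
#' typically 1-3 ms long, so `duration` defaults to 2 ms.
#'
#' @param duration Pulse duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz; must exceed `2 / duration` so the
#'   pulse holds at least a few samples.
#' @param shape `"biphasic"` (one positive and one negative lobe) or
#'   `"triphasic"`.
#' @return An object of class `eod_template`: a list with `samples`
#'   (numeric vector), `sample_rate`, `duration`, `n` (sample count),
#'   `peak_index` (sample of largest |amplitude|, used as the pulse fiducial
#'   point), and `shape`.
#' @examples
#' tpl <- eod_template(0.002, 48828.125)
#' tpl$n
#' max(abs(tpl$samples))
#' @export
eod_template <- function(duration = 0.002, sample_rate = 48828.125,
                         shape = c("biphasic", "triphasic")) {
  shape <- match.arg(shape)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("`duration` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      sample_rate <= 2 / duration) {
    stop("`sample_rate` must exceed 2/duration", call. = FALSE)
  }
  n <- round(duration * sample_rate)
  x <- seq(0, 1, length.out = n)
  hann <- 0.5 * (1 - cos(2 * pi * x))
  carrier <- if (shape == "biphasic") sin(2 * pi * x) else sin(3 * pi * x)
  # head-positive asymmetry: real EODs have a dominant first phase, which
  # also gives the pulse an unambiguous largest-magnitude extremum
  s <- carrier * hann * (1 - 0.4 * x)
  # remove residual mean without disturbing the zero end points
  s <- s - hann * (sum(s) / sum(hann))
  s <- s / max(abs(s))
  structure(
    list(samples = s, sample_rate = sample_rate, duration = duration,
         n = n, peak_index = which.max(abs(s)), shape = shape),
    class = "eod_template"
  )
}

#' @export
print.eod_template <- function(x, ...) {
  cat(sprintf("<eod_template> %s, %.3f ms, %d samples @ %.1f Hz\n",
              x$shape, 1000 * x$duration, x$n, x$sample_rate))
  invisible(x)
}

#' Chirp interval/amplitude profile presets
#'
#' Convenience generator for the per-interval IPI-reduction and per-EOD
#' amplitude-reduction profiles consumed by [inject_chirp()]. Three presets
#' cover the chirp morphologies seen across pulse gymnotiforms:
#' `"single"` -- one shortened interval (the modal chirp in *Microsternarchus*
#' and *Steatogenys*); `"ramp"` -- reductions ramping up to the maximum over
#' the chirp; `"brachy"` -- a long chirp with near-constant deep IPI reduction
#' and an amplitude-reduction maximum near the chirp midpoint, as in
#' *Brachyhypopomus*.
#'
#' @param style Preset name.
#' @param n_eods Number of EODs in the chirp (>= 2); `"single"` forces 2.
#' @param max_ipi_reduction Largest per-interval IPI reduction, percent.
#' @param max_amp_reduction Largest per-EOD amplitude reduction, percent.
#' @return A list with numeric vectors `ipi_reduction` (length `n_eods - 1`)
#'   and `amp_reduction` (length `n_eods`), both in percent.
#' @examples
#' chirp_profile("single", max_ipi_reduction = 44.1)
#' @export
chirp_profile <- function(style = c("single", "ramp", "brachy"),
                          n_eods = 2, max_ipi_reduction = 40,
                          max_amp_reduction = 0) {
  style <- match.arg(style)
  if (style == "single") n_eods <- 2
  n_eods <- as.integer(n_eods)
  if (n_eods < 2) stop("`n_eods` must be >= 2", call. = FALSE)
  m <- n_eods - 1
  ipi <- switch(style,
    single = max_ipi_reduction,
    ramp   = max_ipi_reduction * seq(0.5, 1, length.out = m),
    brachy = max_ipi_reduction * c(seq(0.8, 1, length.out = ceiling(m / 2)),
                                   rep(1, floor(m / 2)))
  )
  # amplitude dip peaks mid-chirp, returning to full amplitude by the end
  mid <- (seq_len(n_eods) - 1) / (n_eods - 1)
  amp <- max_amp_reduction * sin(pi * mid)^2
  if (style == "single") amp <- c(max_amp_reduction, max_amp_reduction) / 2
  list(ipi_reduction = as.numeric(ipi), amp_reduction = as.numeric(amp))
}
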
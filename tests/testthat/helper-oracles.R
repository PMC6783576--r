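# Independent brute-force oracles, deliberately written as plain loops so they
# share no code path with the package implementations they check.

brute_ripi <- function(ipi) {
  out <- rep(NA_real_, length(ipi))
  for (i in seq_along(ipi)) {
    if (i == 1) next
    out[i] <- 100 * (ipi[i - 1] - ipi[i]) / ipi[i - 1]
  }
  out
}

brute_phase <- function(t_s1, first_s2, period) {
  out <- numeric(length(t_s1))
  for (i in seq_along(t_s1)) {
    dt <- t_s1[i] - first_s2
    while (dt >= period) dt <- dt - period
    out[i] <- 360 * dt / period
  }
  out
}

brute_ji <- function(phases) {
  p <- 0L; a <- 0L
  for (ph in phases) {
    if (ph >= 300 && ph < 360) p <- p + 1L
    if (ph >= 0 && ph < 60) a <- a + 1L
  }
  if (p + a == 0) return(NA_real_)
  (p - a) / (p + a)
}

# deterministic interval tibble from an instantaneous-frequency function,
# used to build rise fixtures without the stochastic generator
intervals_from_freq <- function(freq_fun, t_max, t0 = 0) {
  t <- t0
  times <- t
  while (t < t_max) {
    t <- t + 1 / freq_fun(t)
    times <- c(times, t)
  }
  compute_intervals(tibble::tibble(time = times))
}
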
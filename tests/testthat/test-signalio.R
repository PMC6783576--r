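test_that("artifact subtraction removes the stimulus and only the stimulus", {
  tpl <- eod_template(0.002, 48828.125)
  s2 <- s2_schedule(50, 3, 2, phase_offset = 0.3, amplitude = 0.9,
                    template = tpl)
  empty <- synth_baseline_train(50, 2, 0, seed = 1)
  empty$pulses <- empty$pulses[0, ]
  s2_only <- render_waveform(empty, tpl, s2)
  resid <- remove_artifact(s2_only, s2)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(resid$samples), 0.05 * rms(s2_only$samples))
  # no S2 pulses: identity
  s2_none <- s2
  s2_none$times <- numeric(0)
  tr <- synth_baseline_train(50, 2, 0.002, seed = 2)
  rec <- render_waveform(tr, tpl)
  expect_equal(remove_artifact(rec, s2_none)$samples, rec$samples)
  # S1 pulses untouched when the schedules do not overlap: dF = 0 with the
  # S2 placed exactly mid-IPI keeps every S2 pulse 10 ms from every S1 pulse
  s1_times <- tr$pulses$time
  mid_offset <- ((s1_times[1] + 0.01) / 0.02) %% 1
  s2 <- s2_schedule(50, 0, 2, phase_offset = mid_offset, amplitude = 0.9,
                    template = tpl)
  apart <- vapply(s2$times, function(x) min(abs(s1_times - x)), numeric(1))
  expect_gt(min(apart), 0.004)  # fixture sanity: supports disjoint
  cleaned <- remove_artifact(render_waveform(tr, tpl, s2), s2)
  idx <- round(s1_times * tpl$sample_rate) + 1L
  expect_equal(cleaned$samples[idx], rec$samples[idx], tolerance = 1e-9)
  # idempotence
  twice <- remove_artifact(cleaned, s2)
  expect_equal(twice$samples, cleaned$samples, tolerance = 1e-9)
  expect_error(remove_artifact(rec, s2_schedule(50, 0, 5, template = tpl)),
               "outside the recording")
})

test_that("per-pulse artifact fits recover the playback amplitude", {
  tpl <- eod_template(0.002, 48828.125)
  s2 <- s2_schedule(48, 5, 2, phase_offset = 0.1, amplitude = 0.85,
                    template = tpl)
  empty <- synth_baseline_train(48, 2, 0, seed = 3)
  empty$pulses <- empty$pulses[0, ]
  rec <- render_waveform(empty, tpl, s2)
  out <- remove_artifact(rec, s2, method = "per_pulse")
  fits <- attr(out, "fitted_amplitudes")
  expect_equal(unname(fits), rep(0.85, length(s2$times)), tolerance = 1e-6)
})

test_that("pulse detection finds every pulse and respects the refractory rule", {
  tpl <- eod_template(0.002, 48828.125)
  tr <- synth_baseline_train(55, 10, jitter_cv = 0.003, seed = 4)
  rec <- render_waveform(tr, tpl)
  train <- detect_pulses(rec)
  expect_equal(nrow(train), nrow(tr$pulses))
  err <- abs(train$time - tr$pulses$time)
  expect_lt(max(err), 2e-4)
  expect_true(all(train$amplitude > 0))
  # silent recording: empty train, not an error
  silent <- chirpjar:::new_eod_recording(numeric(1000), 48828.125)
  expect_equal(nrow(detect_pulses(silent)), 0)
  # two template copies 0.5 ms apart merge under a 1 ms refractory
  x <- numeric(5000)
  p1 <- 2000L
  p2 <- p1 + round(0.0005 * 48828.125)
  for (p in c(p1, p2)) {
    idx <- p - (tpl$peak_index - 1L) + seq_len(tpl$n) - 1L
    x[idx] <- x[idx] + tpl$samples
  }
  two <- chirpjar:::new_eod_recording(x, 48828.125)
  expect_equal(nrow(detect_pulses(two, refractory = 0.001)), 1)
  # the same pair 5 ms apart stays two events
  y <- numeric(5000)
  for (p in c(p1, p1 + round(0.005 * 48828.125))) {
    idx <- p - (tpl$peak_index - 1L) + seq_len(tpl$n) - 1L
    y[idx] <- y[idx] + tpl$samples
  }
  apart <- chirpjar:::new_eod_recording(y, 48828.125)
  expect_equal(nrow(detect_pulses(apart, refractory = 0.001)), 2)
  expect_error(detect_pulses(rec, threshold = 1.5), "threshold")
})

test_that("detected pulse count is non-increasing in threshold", {
  trial <- synth_trial(60, 4, jitter_cv = 0.004, seed = 5, noise_sd = 0.02,
    events = list(list(type = "chirp", onset_time = 2, ipi_reduction = 50,
                       amp_reduction = c(40, 40))))
  clean <- remove_artifact(trial$recording, trial$s2)
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.7, 0.9),
                   function(th) nrow(detect_pulses(clean, threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("interval series carries IPI, frequency and rIPI", {
  iv <- compute_intervals(tibble::tibble(time = c(0, 0.020, 0.038)))
  expect_equal(iv$ipi, c(0.020, 0.018))
  expect_equal(iv$ripi, c(NA, 10))
  expect_equal(iv$freq * iv$ipi, c(1, 1))
  # constant IPIs: all rIPI zero
  cst <- compute_intervals(tibble::tibble(time = seq(0, 1, by = 0.02)))
  expect_equal(cst$ripi[-1], rep(0, nrow(cst) - 1))
  # the modal single-interval chirp: 20 -> 11.18 ms is a 44.1% reduction
  ch <- compute_intervals(tibble::tibble(time = c(0, 0.020, 0.03118)))
  expect_equal(ch$ripi[2], 44.1)
  expect_error(compute_intervals(tibble::tibble(time = 1)), "2 pulses")
  expect_error(compute_intervals(tibble::tibble(time = c(1, 1))),
               "strictly increasing")
})

test_that("rIPI equals the brute-force two-pass oracle exactly", {
  withr::with_seed(42, {
    for (k in 1:50) {
      n <- sample(5:40, 1)
      ipi <- runif(n, 0.005, 0.05)
      iv <- compute_intervals(tibble::tibble(time = cumsum(c(0, ipi))))
      expect_equal(iv$ripi, brute_ripi(ipi))
    }
  })
})

test_that("baseline statistics summarize resting discharge", {
  flat <- compute_intervals(synth_baseline_train(50, 70, 0, seed = 6)$pulses)
  bs <- baseline_stats(flat)
  expect_equal(bs$mean_freq, 50, tolerance = 1e-9)
  expect_equal(bs$ripi_sd, 0, tolerance = 1e-6)
  # a jitter CV of 0.27/(100 sqrt(2)) reproduces a 0.27% rIPI SD:
  # for independent Gaussian IPIs, sd(rIPI) ~ 100 sqrt(2) cv
  cv <- 0.27 / (100 * sqrt(2))
  tr <- synth_baseline_train(55, 70, cv, seed = 7)
  iv <- compute_intervals(tr$pulses)
  expect_gt(nrow(iv), 3000)
  bs2 <- baseline_stats(iv, window = 70)
  expect_lt(abs(bs2$ripi_sd - 0.27) / 0.27, 0.15)
  # two disjoint windows of a stationary train agree within 2 SE
  tr2 <- synth_baseline_train(55, 120, 0.005, seed = 8)
  iv2 <- compute_intervals(tr2$pulses)
  a <- baseline_stats(iv2[iv2$t_start < 60, ], window = 60)
  b <- baseline_stats(iv2[iv2$t_start >= 60, ], window = 60)
  expect_lt(abs(a$mean_freq - b$mean_freq), 2 * (a$freq_se + b$freq_se))
  expect_error(baseline_stats(flat[1:5, ]), "10 intervals")
})
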
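test_that("EOD template is normalized, zero-mean and deterministic", {
  tpl <- eod_template(0.002, 48828.125)
  expect_equal(tpl$n, round(0.002 * 48828.125))
  expect_equal(max(abs(tpl$samples)), 1)
  expect_lt(abs(sum(tpl$samples)), 1e-9)
  expect_equal(tpl$samples[1], 0)
  expect_equal(tpl$samples[tpl$n], 0, tolerance = 1e-12)
  expect_identical(tpl$samples, eod_template(0.002, 48828.125)$samples)
  tri <- eod_template(0.002, 48828.125, shape = "triphasic")
  expect_lt(abs(sum(tri$samples)), 1e-9)
  expect_error(eod_template(-1, 48828.125), "duration")
  expect_error(eod_template(0.002, 500), "sample_rate")
})

test_that("baseline train realizes the requested rate and jitter", {
  tr <- synth_baseline_train(50, 1, jitter_cv = 0, seed = 1)
  expect_equal(nrow(tr$pulses), 50)
  expect_equal(diff(tr$pulses$time), rep(0.02, 49))
  # empirical IPI CV matches the requested CV at large n
  tr2 <- synth_baseline_train(50, 120, jitter_cv = 0.005, seed = 2)
  ipi <- diff(tr2$pulses$time)
  expect_gt(length(ipi), 5000)
  expect_lt(abs(sd(ipi) / mean(ipi) - 0.005) / 0.005, 0.1)
  expect_error(synth_baseline_train(0, 1), "frequency")
  expect_error(synth_baseline_train(50, 1, jitter_cv = 0.6), "jitter_cv")
  # bit-identical under a fixed seed
  a <- synth_baseline_train(60, 5, 0.01, seed = 99)
  b <- synth_baseline_train(60, 5, 0.01, seed = 99)
  expect_identical(a$pulses, b$pulses)
})

test_that("chirp injection shortens intervals against the pre-chirp IPI", {
  tr <- synth_baseline_train(50, 2, jitter_cv = 0, seed = 1)
  t0 <- tr$pulses$time
  # 44.1% single-interval reduction of a 20 ms IPI gives 11.18 ms
  ch <- inject_chirp(tr, 20, ipi_reduction = 44.1)
  expect_equal(diff(ch$pulses$time)[20], 0.02 * (1 - 0.441))
  expect_equal(nrow(ch$events), 1L)
  # zero reduction: times unchanged, event still recorded
  id <- inject_chirp(tr, 20, ipi_reduction = 0)
  expect_equal(id$pulses$time, t0)
  expect_equal(nrow(id$events), 1L)
  # [50, 50] on 20 ms IPIs: two 10 ms intervals, tail 20 ms earlier
  two <- inject_chirp(tr, 20, ipi_reduction = c(50, 50))
  expect_equal(diff(two$pulses$time)[20:21], c(0.01, 0.01))
  expect_equal(two$pulses$time[30], t0[30] - 0.02)
  expect_equal(nrow(two$pulses), nrow(tr$pulses))
  expect_error(inject_chirp(tr, 200, ipi_reduction = 50), "out of range")
  expect_error(inject_chirp(tr, 20, 50, amp_reduction = c(1, 2, 3)), "length")
  # amplitude profile applied to chirp EODs
  amp <- inject_chirp(tr, 20, 50, amp_reduction = c(10, 30))
  expect_equal(amp$pulses$amplitude[20:21], c(0.9, 0.7))
})

test_that("tumultuous rise injection ramps frequency and intersperses chirps", {
  tr <- synth_baseline_train(55, 15, jitter_cv = 0, seed = 3)
  r <- inject_tumultuous_rise(tr, 4, 6.65, rise_hz = 34.3,
                              chirp_rate = 15.61)
  ev <- r$events[r$events$type == "rise", ]
  expect_equal(nrow(ev), 1L)
  # mid-rise plateau: median instantaneous frequency of baseline intervals
  # near 55 + 34.3 = 89.3 Hz (median is robust to the chirp intervals)
  iv <- compute_intervals(r$pulses)
  mid <- iv$freq[iv$t_start > 6.5 & iv$t_end < 8.5]
  expect_lt(abs(median(mid) - 89.3), 3)
  # chirp-like interval count close to chirp_rate * duration
  expect_lt(abs(ev$detail[[1]]$n_chirp_intervals - 15.61 * 6.65), 4)
  # vanishing rise with no chirps leaves a zero-jitter train unchanged
  r0 <- inject_tumultuous_rise(tr, 4, 2, rise_hz = 1e-9, chirp_rate = 0)
  expect_equal(r0$pulses$time, tr$pulses$time, tolerance = 1e-6)
  expect_error(inject_tumultuous_rise(tr, 4, 0.2, 30), "duration")
  expect_error(inject_tumultuous_rise(tr, 4, 2, -1), "rise_hz")
  expect_error(
    inject_tumultuous_rise(inject_tumultuous_rise(tr, 4, 2, 20), 5, 2, 20),
    "overlap")
})

test_that("interruption injection removes pulses and preserves the count ledger", {
  tr <- synth_baseline_train(50, 10, jitter_cv = 0, seed = 4)
  n0 <- nrow(tr$pulses)
  it <- inject_interruption(tr, 5, 0.06, hash_fraction = 0.5)
  ev <- it$events[1, ]
  d <- ev$detail[[1]]
  expect_equal(d$n_removed, 3L)   # a 60 ms window of a 50 Hz train
  expect_equal(nrow(it$pulses), n0 - d$n_removed)
  expect_equal(d$hash_end, 5.03)
  # the silence spans exactly [start, start + duration]
  t <- it$pulses$time
  expect_true(any(abs(t - 5) < 1e-9) && any(abs(t - 5.06) < 1e-9))
  expect_equal(max(diff(t)), 0.06)
  # sub-IPI interruption between pulses removes nothing but is recorded
  tr2 <- synth_baseline_train(50, 2, jitter_cv = 0, seed = 5)
  start <- tr2$pulses$time[30] + 0.002
  it2 <- inject_interruption(tr2, start, 0.01)
  expect_equal(it2$events$detail[[1]]$n_removed, 0L)
  expect_equal(nrow(it2$events), 1L)
  expect_error(inject_interruption(tr, 5, -1), "duration")
})

test_that("S2 schedule has a fixed period covering the trial", {
  s2 <- s2_schedule(50, 2, 10)
  expect_equal(s2$period, 1 / 52)
  expect_equal(length(s2$times), 520)
  expect_equal(diff(s2$times), rep(1 / 52, 519), tolerance = 1e-10)
  expect_equal(s2_schedule(50, 0, 10)$period, 0.02)
  expect_error(s2_schedule(50, -50, 10), "must be > 0")
  off <- s2_schedule(50, 0, 1, phase_offset = 0.25)
  expect_equal(off$times[1], 0.005)
})

test_that("rendering is additive, aligned and deterministic", {
  tpl <- eod_template(0.002, 48828.125)
  tr <- synth_baseline_train(50, 0.5, jitter_cv = 0, seed = 6)
  one <- tr
  one$pulses <- one$pulses[5, ]
  rec <- render_waveform(one, tpl)
  i0 <- round(one$pulses$time * tpl$sample_rate) + 1L
  expect_equal(rec$samples[i0], tpl$samples[tpl$peak_index])
  expect_equal(sum(abs(rec$samples) > 0), sum(abs(tpl$samples) > 0))
  # linearity: S1-only + S2-only = joint (noise off)
  s2 <- s2_schedule(50, 3, 0.5, phase_offset = 0.4, template = tpl)
  joint <- render_waveform(tr, tpl, s2)
  s1_only <- render_waveform(tr, tpl)
  empty <- tr
  empty$pulses <- tr$pulses[0, ]
  s2_only <- render_waveform(empty, tpl, s2)
  expect_equal(joint$samples, s1_only$samples + s2_only$samples)
  # determinism with sensor noise under a fixed seed
  n1 <- render_waveform(tr, tpl, noise_sd = 0.01, seed = 7)
  n2 <- render_waveform(tr, tpl, noise_sd = 0.01, seed = 7)
  expect_identical(n1$samples, n2$samples)
})

test_that("noise-free renderings round-trip through detection", {
  trial <- synth_trial(55, 10, jitter_cv = 0.003, dF = 4, seed = 8,
                       noise_sd = 0)
  clean <- remove_artifact(trial$recording, trial$s2)
  train <- detect_pulses(clean)
  tt <- trial$truth$pulses$time
  err <- vapply(tt, function(x) min(abs(train$time - x)), numeric(1))
  expect_gte(mean(err < 2e-4), 0.99)
})

test_that("recording and schedule files round-trip", {
  tmp <- withr::local_tempdir()
  trial <- synth_trial(50, 1, seed = 9, noise_sd = 0.01)
  stem <- file.path(tmp, "rec")
  write_recording(trial$recording, stem)
  back <- read_recording(stem)
  expect_equal(back$sample_rate, trial$recording$sample_rate)
  expect_equal(back$samples, trial$recording$samples, tolerance = 1e-6)
  sp <- file.path(tmp, "s2.json")
  write_s2_schedule(trial$s2, sp)
  s2b <- read_s2_schedule(sp)
  expect_equal(s2b$times, trial$s2$times)
  expect_equal(s2b$period, trial$s2$period)
  write_ground_truth(trial$truth, file.path(tmp, "gt"))
  pulses <- utils::read.csv(file.path(tmp, "gt_pulses.csv"))
  expect_equal(nrow(pulses), nrow(trial$truth$pulses))
})
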
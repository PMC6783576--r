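test_that("phase angles are measured against the preceding S2 pulse", {
  s2 <- s2_schedule(50, 0, 1, phase_offset = 0)
  ph <- compute_phases(tibble::tibble(time = c(0.010, 0.020, 0.038889)), s2)
  expect_equal(ph$phase, c(180, 0, 340), tolerance = 1e-3)
  # S1 before the first S2 is excluded and counted
  s2b <- s2_schedule(50, 0, 1, phase_offset = 0.5)
  phb <- compute_phases(tibble::tibble(time = c(0.001, 0.02)), s2b)
  expect_equal(nrow(phb), 1L)
  expect_equal(attr(phb, "n_skipped"), 1L)
})

test_that("phases match the independent modulo oracle exactly", {
  withr::with_seed(41, {
    for (k in 1:50) {
      f2 <- runif(1, 30, 90)
      s2 <- s2_schedule(f2, 0, 2, phase_offset = runif(1))
      t_s1 <- sort(runif(20, s2$times[1], 2))
      ph <- compute_phases(tibble::tibble(time = t_s1), s2)
      expect_equal(ph$phase, brute_phase(t_s1, s2$times[1], s2$period),
                   tolerance = 1e-9)
    }
  })
})

test_that("the critical window converts degrees to time", {
  expect_equal(round(critical_window_ms(50) * 1000, 1), 6.7)
  expect_equal(critical_window_ms(50, 360), 0.02)
  expect_equal(round(critical_window_ms(100) * 1000, 1), 3.3)
  expect_error(critical_window_ms(0), "frequency")
})

test_that("jamming index counts the 60-degree windows around coincidence", {
  expect_equal(jamming_index(c(10, 25, 40, 55))$ji, -1)
  expect_equal(jamming_index(c(305, 320, 340, 355))$ji, 1)
  j <- jamming_index(c(10, 350, 180))
  expect_equal(j$ji, 0)
  expect_equal(j$n_critical, 2L)   # 180 degrees is outside the window
  expect_true(is.na(jamming_index(c(100, 200))$ji))
  # invariance to angles outside the critical window
  expect_equal(jamming_index(c(10, 350, 90, 120, 250))$ji,
               jamming_index(c(10, 350))$ji)
})

test_that("ji is antisymmetric under phase reflection", {
  withr::with_seed(42, {
    for (k in 1:25) {
      ph <- runif(sample(3:30, 1), 0, 360)
      a <- jamming_index(ph)$ji
      b <- jamming_index((360 - ph) %% 360)$ji
      if (is.na(a)) expect_true(is.na(b)) else expect_equal(b, -a)
    }
  })
})

test_that("windowed ji matches the brute-force oracle", {
  withr::with_seed(43, {
    for (k in 1:50) {
      ph <- runif(sample(1:40, 1), 0, 360)
      expect_identical(jamming_index(ph)$ji, brute_ji(ph))
    }
  })
})

test_that("the permutation null is correct and its z-scores standard", {
  expect_equal(jamming_null_z(0, 10, reps = 200, seed = 1)$z, 0)
  expect_false(jamming_null_z(NA_real_, 0)$significant)
  # null SD at n = 12 agrees with a high-rep brute-force simulation
  sd_pkg <- jamming_null_sd(12, reps = 10000, seed = 2)
  sd_oracle <- withr::with_seed(3, {
    reps <- 1e6
    ph <- matrix(runif(reps * 12, 0, 360), nrow = reps)
    p <- rowSums(ph >= 300); a <- rowSums(ph < 60); k <- p + a
    sd(((p - a) / k)[k > 0])
  })
  expect_lt(abs(sd_pkg - sd_oracle) / sd_oracle, 0.03)
  # z-scores under the uniform null have approximately unit SD
  z <- withr::with_seed(4, {
    sds <- vapply(5:30, function(n) jamming_null_sd(n, 4000), numeric(1))
    replicate(4000, {
      n <- sample(5:30, 1)
      ji <- jamming_index(runif(n, 0, 360))$ji
      if (is.na(ji)) NA_real_ else ji / sds[n - 4]
    })
  })
  expect_gt(sd(z, na.rm = TRUE), 0.9)
  expect_lt(sd(z, na.rm = TRUE), 1.1)
})

test_that("the jamming profile tiles the trial and flags phase-locked spans", {
  # 10 s trial, 400 ms window, 50% overlap: 49 full windows
  trial <- synth_trial(55, 10, seed = 44, render = FALSE)
  prof <- jamming_profile(trial$truth$pulses, trial$s2, reps = 500,
                          seed = 1, trial_duration = 10)
  expect_equal(nrow(prof), 49L)
  expect_false(any(prof$partial))
  # S1 pulses placed just before every S2: strongly positive, significant
  s2 <- s2_schedule(50, 0, 10, phase_offset = 0.5)
  train <- tibble::tibble(time = s2$times - 0.002)
  train <- train[train$time > s2$times[1], , drop = FALSE]
  prof2 <- jamming_profile(train, s2, reps = 2000, seed = 2,
                           trial_duration = 10)
  expect_true(all(prof2$ji == 1))
  expect_gt(mean(prof2$significant), 0.95)
  spans <- summarize_jamming(prof2)
  expect_true(all(spans$sign == 1))
  # a trial shorter than one window yields a single flagged partial window
  short <- jamming_profile(tibble::tibble(time = c(0.05, 0.1, 0.2)),
                           s2_schedule(50, 0, 0.3), window = 0.4,
                           reps = 200, seed = 3, trial_duration = 0.3)
  expect_equal(nrow(short), 1L)
  expect_true(short$partial)
})

test_that("uniform phases are flagged significant at the nominal rate", {
  res <- withr::with_seed(45, {
    sds <- vapply(5:30, function(n) jamming_null_sd(n, 4000), numeric(1))
    replicate(3000, {
      n <- sample(5:30, 1)
      ji <- jamming_index(runif(n, 0, 360))$ji
      if (is.na(ji)) NA else abs(ji / sds[n - 4]) > 1.96
    })
  })
  rate <- mean(res, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("circular summaries match closed-form expectations", {
  one <- circular_summary(rep(90, 12))
  expect_equal(one$mean_angle, 90)
  expect_equal(one$resultant_r, 1)
  expect_equal(one$circ_sd, 0)
  sym <- circular_summary(c(0, 90, 180, 270))
  expect_equal(sym$resultant_r, 0, tolerance = 1e-12)
  expect_equal(sym$rayleigh_p, 1, tolerance = 1e-6)
  # von Mises recovery: A(1) = I1(1)/I0(1) ~ 0.446
  ang <- rvonmises(100, mu = 200, kappa = 1, seed = 46)
  cs <- circular_summary(ang)
  d <- abs(((cs$mean_angle - 200 + 180) %% 360) - 180)
  expect_lt(d, 15)
  a1 <- besselI(1, 1) / besselI(1, 0)
  expect_lt(abs(cs$resultant_r - a1), 0.1)
  expect_error(circular_summary(numeric(0)), "angle")
})

test_that("the Rayleigh approximation holds its nominal size", {
  p <- withr::with_seed(47, {
    replicate(4000, circular_summary(runif(20, 0, 360))$rayleigh_p)
  })
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("chirp phase statistics pool trials per subject", {
  ch <- tibble::tibble(start_phase = rep(240, 5), trial = c(1, 1, 1, 2, 2))
  st <- chirp_phase_stats(ch)
  expect_equal(nrow(st$per_trial), 2L)
  expect_equal(st$per_trial$circ_sd, c(0, 0))
  expect_equal(st$pooled$mean_angle, 240)
  # pooling equals a circular summary of the concatenated angles
  ang <- rvonmises(50, mu = 233, kappa = 2, seed = 48)
  ch2 <- tibble::tibble(start_phase = ang,
                        trial = rep(1:5, each = 10))
  st2 <- chirp_phase_stats(ch2)
  expect_equal(st2$pooled[, c("mean_angle", "resultant_r", "rayleigh_p")],
               circular_summary(ang)[, c("mean_angle", "resultant_r",
                                         "rayleigh_p")])
  expect_true(st2$pooled$significant)
  d <- abs(((st2$pooled$mean_angle - 233 + 180) %% 360) - 180)
  expect_lt(d, 10)
  # single-chirp trials are excluded from within-trial statistics
  ch3 <- tibble::tibble(start_phase = c(10, 20, 200), trial = c(1, 1, 2))
  expect_equal(nrow(chirp_phase_stats(ch3)$per_trial), 1L)
})
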
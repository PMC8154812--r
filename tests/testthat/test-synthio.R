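test_that("parameter invariants are enforced with the offending field named", {
  expect_error(pump_sound_params(normal_rpm = 7000), "normal_rpm")
  expect_error(pump_sound_params(ils_rpm = 11000, normal_rpm = 10000), "ils_rpm")
  expect_error(pump_sound_params(ils_duration = 70, ils_period = 64),
               "ils_duration")
  expect_error(pump_sound_params(duration = 30), "duration")
  expect_error(pump_sound_params(heart_rate = 200), "heart_rate")
  expect_error(pump_sound_params(resp_rate = 40), "resp_rate")
  expect_error(pump_sound_params(n_harmonics = 2,
                                 harmonic_amplitudes = c(1, 0.1)),
               "n_harmonics")
  expect_error(pump_sound_params(sample_rate = 500), "sample_rate")
})

test_that("unmodulated recording has its strongest spectral line at rpm/60", {
  # FFT oracle: 10,000 rpm corresponds to a 167 Hz peak
  p <- pump_sound_params(normal_rpm = 10000, ils_enabled = FALSE,
                         freq_mod_depth = 0, ils_freq_mod_depth = 0,
                         amp_mod_depth = 0, ils_amp_mod_depth = 0,
                         band_noise_levels = c(0, 0, 0),
                         duration = 8, sample_rate = 8000, seed = 7)
  x <- simulate_recording(p)$recording$samples
  sp <- Mod(stats::fft(x))[1:(length(x) / 2)]
  f_peak <- (which.max(sp) - 1) * 8000 / length(x)
  expect_equal(f_peak, 10000 / 60, tolerance = 0.25)  # within one FFT bin
  expect_equal(round(f_peak), 167)
})

test_that("spectral placement holds across the normal rpm range", {
  for (rpm in c(8000, 9500, 12000)) {
    p <- pump_sound_params(normal_rpm = rpm, ils_enabled = FALSE,
                           freq_mod_depth = 0, amp_mod_depth = 0,
                           band_noise_levels = c(0, 0, 0),
                           duration = 4, sample_rate = 8000, seed = 1)
    x <- simulate_recording(p)$recording$samples
    sp <- Mod(stats::fft(x))[1:(length(x) / 2)]
    f_peak <- (which.max(sp) - 1) * 8000 / length(x)
    expect_equal(f_peak, rpm / 60, tolerance = 8000 / length(x) * 1.5)
  }
})

test_that("ground truth lists the planted ILS windows", {
  sim <- fx_protocol_sim()
  gt <- sim$ground_truth
  expect_equal(nrow(gt$ils_segments), 2)
  expect_equal(unname(gt$ils_segments[, "end"] - gt$ils_segments[, "start"]),
               c(8, 8))
  expect_equal(unname(diff(gt$ils_segments[, "start"])), 64)
  expect_true(all(gt$ils_segments >= 0 & gt$ils_segments <= 128))

  none <- simulate_recording(pump_sound_params(ils_enabled = FALSE,
                                               duration = 4,
                                               sample_rate = 8000))
  expect_equal(nrow(none$ground_truth$ils_segments), 0)
})

test_that("zero harmonic amplitudes and zero noise give a silent recording", {
  p <- pump_sound_params(harmonic_amplitudes = c(0, 0, 0),
                         band_noise_levels = c(0, 0, 0),
                         duration = 64.5, ils_period = 64, sample_rate = 4000)
  x <- simulate_recording(p)$recording$samples
  expect_true(all(x == 0))
})

test_that("identical seeds give bit-identical samples, different seeds differ", {
  p <- pump_sound_params(duration = 64.5, sample_rate = 4000, seed = 42)
  a <- simulate_recording(p)$recording$samples
  b <- simulate_recording(p)$recording$samples
  expect_identical(a, b)
  p2 <- pump_sound_params(duration = 64.5, sample_rate = 4000, seed = 43)
  expect_false(identical(a, simulate_recording(p2)$recording$samples))
})

test_that("cohort labeling matches the requested prevalence", {
  pars <- sample_cohort_params(cohort_spec(245, ar_prevalence = 26 / 245,
                                           seed = 5))
  expect_equal(nrow(pars), 245)
  expect_equal(sum(pars$ar_label), 26)

  none <- sample_cohort_params(cohort_spec(40, ar_prevalence = 0, seed = 5))
  expect_true(all(none$ar_label == 0))
  expect_error(cohort_spec(0), "empty cohort")
  expect_error(cohort_spec(10, ar_prevalence = 1.2), "prevalence")
})

test_that("planted parameter means converge to the class means", {
  # oracle: direct average of the planted values against the class mean
  pars <- sample_cohort_params(cohort_spec(400, ar_prevalence = 0.5, seed = 9))
  ar <- pars[pars$ar_label == 1, ]
  se <- 1001 / sqrt(nrow(ar))
  expect_lt(abs(mean(ar$ils_rpm) - 7072), 2 * se + 15)  # +15: truncation shift
  nonar <- pars[pars$ar_label == 0, ]
  expect_lt(abs(mean(nonar$normal_rpm) - 10033), 2 * 809 / sqrt(nrow(nonar)) + 25)
  expect_lt(abs(mean(nonar$heart_rate) - 84), 2 * 14 / sqrt(nrow(nonar)) + 2)
})

test_that("ground truth round-trips losslessly through the JSON sidecar", {
  sim <- fx_protocol_sim()
  p <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, p)
  back <- read_ground_truth(p)
  expect_equal(back$params, sim$ground_truth$params)
  expect_equal(back$ils_segments, sim$ground_truth$ils_segments)

  none <- simulate_recording(pump_sound_params(ils_enabled = FALSE,
                                               duration = 2,
                                               sample_rate = 8000))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(none$ground_truth, p2)
  expect_equal(nrow(read_ground_truth(p2)$ils_segments), 0)
})

test_that("feature-level cohorts plant the class contrasts", {
  tab <- simulate_feature_table(245, ar_prevalence = 26 / 245, seed = 4)
  expect_s3_class(tab, "feature_table")
  expect_equal(sum(tab$ar_label), 26)
  expect_equal(ncol(as.data.frame(tab)[, feature_names()]), 19)

  # multiplier 0 removes every contrast; ablation switch removes one
  t0 <- simulate_feature_table(600, 0.5, effect_multiplier = 0, seed = 4)
  d_ils <- mean(t0$rpm_ils[t0$ar_label == 1]) - mean(t0$rpm_ils[t0$ar_label == 0])
  expect_lt(abs(d_ils), 200)
  t1 <- simulate_feature_table(600, 0.5, effect_multiplier = 1,
                               effects = c(ils_rpm = FALSE), seed = 4)
  d_off <- mean(t1$rpm_ils[t1$ar_label == 1]) - mean(t1$rpm_ils[t1$ar_label == 0])
  expect_lt(abs(d_off), 200)
  t2 <- simulate_feature_table(600, 0.5, effect_multiplier = 1, seed = 4)
  d_on <- mean(t2$rpm_ils[t2$ar_label == 1]) - mean(t2$rpm_ils[t2$ar_label == 0])
  expect_lt(d_on, -200)  # AR class has lower ILS rotational speed
})
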
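test_that("fluctuation spectrum recovers planted modulation amplitude and frequency", {
  dt <- 0.01
  t <- seq(0, 30, by = dt)
  # planted 1.4 Hz modulation with 4.2 Hz peak deviation on a 167 Hz carrier
  track <- 167 + 4.2 * sin(2 * pi * 1.4 * t + 0.7)
  fs <- fluctuation_spectrum(track, dt)
  pk <- dominant_peak(fs, c(0.5, 5))
  expect_equal(pk$frequency, 1.4, tolerance = 0.02 / 1.4)
  expect_equal(pk$amplitude, 4.2, tolerance = 0.2 / 4.2)

  # constant track: nothing above numerical noise
  fs0 <- fluctuation_spectrum(rep(167, length(t)), dt)
  expect_lt(max(fs0$amplitudes[fs0$frequencies > 0.1]), 1e-9)

  # two planted modulations give two distinct peaks
  tr2 <- 80 + 9 * sin(2 * pi * 0.33 * t) + 5 * sin(2 * pi * 1.4 * t)
  fs2 <- fluctuation_spectrum(tr2, dt)
  p_lo <- dominant_peak(fs2, c(0.15, 0.7))
  p_hi <- dominant_peak(fs2, c(0.7, 3))
  expect_equal(p_lo$frequency, 0.33, tolerance = 0.05 / 0.33)
  expect_equal(p_lo$amplitude, 9, tolerance = 0.05)
  expect_equal(p_hi$frequency, 1.4, tolerance = 0.02 / 1.4)
  expect_equal(p_hi$amplitude, 5, tolerance = 0.05)
})

test_that("fluctuation spectrum enforces its data requirements", {
  expect_error(fluctuation_spectrum(rnorm(500), 0.01), "insufficient data")
  x <- rnorm(2000)
  x[sample(2000, 500)] <- NA  # 25% gaps
  expect_error(fluctuation_spectrum(x, 0.01), "gaps")
  x2 <- sin(2 * pi * 1.4 * seq(0, 20, by = 0.01))
  x2[5:50] <- NA  # small gap: bridged with a note
  expect_message(fs <- fluctuation_spectrum(x2, 0.01), "bridging")
  expect_equal(dominant_peak(fs, c(0.7, 3))$frequency, 1.4, tolerance = 0.02)
})

test_that("heart rate is read from the cardiac band of the frequency spectrum", {
  dt <- 0.01; t <- seq(0, 30, by = dt)
  fs84 <- fluctuation_spectrum(167 + 4.2 * sin(2 * pi * 1.4 * t), dt)
  expect_equal(extract_heart_rate(fs84), 84, tolerance = 0.5 / 84)
  fs60 <- fluctuation_spectrum(167 + 4.2 * sin(2 * pi * 1.0 * t), dt)
  expect_equal(extract_heart_rate(fs60), 60, tolerance = 0.5 / 60)
  # no modulation: flagged missing
  fs_none <- fluctuation_spectrum(rep(167, length(t)), dt)
  expect_true(is.na(extract_heart_rate(fs_none)))
})

test_that("respiratory rate is read below 0.5 Hz of the amplitude spectrum", {
  dt <- 0.01; t <- seq(0, 30, by = dt)
  fs20 <- fluctuation_spectrum(80 + 9 * sin(2 * pi * (20 / 60) * t), dt)
  expect_equal(extract_respiratory_rate(fs20), 20, tolerance = 0.3 / 20)
  fs15 <- fluctuation_spectrum(80 + 9 * sin(2 * pi * 0.25 * t), dt)
  expect_equal(extract_respiratory_rate(fs15), 15, tolerance = 0.3 / 15)
  fs_none <- fluctuation_spectrum(rep(80, length(t)), dt)
  expect_true(is.na(extract_respiratory_rate(fs_none)))
})

test_that("band amplitudes are near zero for a noise-free harmonic stack", {
  p <- pump_sound_params(ils_enabled = FALSE, band_noise_levels = c(0, 0, 0),
                         duration = 20, sample_rate = 8000, seed = 2)
  map <- normalize_amplitude(gabor_scalogram(simulate_recording(p)$recording))
  ba <- band_amplitudes(map, 10000 / 60)
  expect_true(all(ba < 1.5))  # a.u.; harmonic neighborhoods excised
  expect_true(all(is.na(band_amplitudes(map, NA))))
})

test_that("band amplitudes track the planted noise levels", {
  mk <- function(levels, seed) {
    p <- pump_sound_params(ils_enabled = FALSE, band_noise_levels = levels,
                           freq_mod_depth = 0, amp_mod_depth = 0,
                           duration = 20, sample_rate = 8000, seed = seed)
    map <- normalize_amplitude(gabor_scalogram(simulate_recording(p)$recording))
    band_amplitudes(map, 10000 / 60)
  }
  base <- mk(c(6.6, 4.4, 1.2), 5)
  expect_true(base[["low"]] > base[["middle"]])
  expect_true(base[["middle"]] > base[["high"]])
  # doubling the middle-band noise doubles the recovered middle amplitude
  doubled <- mk(c(6.6, 8.8, 1.2), 5)
  expect_equal(doubled[["middle"]] / base[["middle"]], 2, tolerance = 0.1)
  expect_equal(doubled[["low"]] / base[["low"]], 1, tolerance = 0.1)
  expect_equal(doubled[["high"]] / base[["high"]], 1, tolerance = 0.1)
})

test_that("extraction yields exactly 19 features in catalogue order", {
  fv <- fx_protocol_features()
  expect_length(fv$values, 19)
  expect_identical(names(fv$values), feature_names())
  expect_true(all(!fv$missing))
  expect_equal(nrow(feature_catalogue()), 19)
})

test_that("planted values are recovered on the protocol recording", {
  v <- fx_protocol_features()$values
  expect_equal(v[["rpm_normal"]], 10033, tolerance = 60 / 10033)
  expect_equal(v[["rpm_ils"]], 7000, tolerance = 60 / 7000)
  expect_equal(v[["heart_rate"]], 84, tolerance = 3 / 84)
  expect_equal(v[["resp_rate"]], 20, tolerance = 1.5 / 20)
  expect_equal(v[["freqvar_h1"]], 4.2, tolerance = 0.1)   # wavelet smoothing bias < 10%
  expect_equal(v[["freq_h2"]], 2 * v[["freq_h1"]], tolerance = 1 / 334)
  expect_equal(v[["freq_h3"]], 3 * v[["freq_h1"]], tolerance = 1.5 / 500)
})

test_that("a recording without an ILS window has exactly the 3 ILS features missing", {
  p <- pump_sound_params(ils_enabled = FALSE, duration = 66, seed = 13)
  fv <- suppressWarnings(suppressMessages(
    extract_features(simulate_recording(p)$recording)))
  expect_equal(sum(fv$missing), 3)
  expect_true(all(fv$missing[c("rpm_ils", "ils_freqvar_h1", "ils_ampvar_h1")]))
  expect_equal(sum(!fv$missing), 16)
})

test_that("features are invariant under positive rescaling of the waveform", {
  p <- pump_sound_params(duration = 66, seed = 17)
  sim <- simulate_recording(p)
  fv1 <- suppressMessages(extract_features(sim$recording))
  scaled <- sim$recording
  scaled$samples <- scaled$samples * 41.7
  fv2 <- suppressMessages(extract_features(scaled))
  expect_equal(fv2$values, fv1$values, tolerance = 1e-9)
})

test_that("an unanalyzable recording raises a structured extraction error", {
  silent <- recording(rep(0, 66 * 4000), 4000, recording_id = "mute")
  err <- tryCatch(suppressWarnings(extract_features(silent)),
                  error = function(e) e)
  expect_s3_class(err, "lvad_extraction_error")
  expect_match(conditionMessage(err), "mute")
})
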
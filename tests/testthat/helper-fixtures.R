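# Shared fixtures, computed once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# pure tone recording (defaults chosen so scalograms stay cheap)
tone_recording <- function(freq, duration = 4, fs = 8000, amp = 1, id = "tone") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  recording(amp * sin(2 * pi * freq * t), fs, recording_id = id)
}

# minimal peak_track for segmentation / spectrum unit tests
make_track <- function(freq, time_step = 0.01, amplitude = NULL) {
  n <- length(freq)
  structure(list(times = (seq_len(n) - 0.5) * time_step,
                 frequency = freq,
                 amplitude = if (is.null(amplitude)) rep(80, n) else amplitude,
                 harmonic_index = 1L),
            class = "peak_track")
}

# the 128 s protocol recording: 10033 rpm normal speed, standard ILS protocol
# (7000 rpm for 8 s every 64 s), reference heart (84 bpm) and respiratory
# (20/min) rates
fx_protocol_sim <- function() {
  fx_cached("protocol_sim",
            simulate_recording(pump_sound_params(normal_rpm = 10033, seed = 101),
                               recording_id = "protocol"))
}

fx_protocol_analysis <- function() {
  fx_cached("protocol_analysis", {
    sim <- fx_protocol_sim()
    map <- normalize_amplitude(gabor_scalogram(sim$recording))
    h1 <- track_harmonic(map, c(6500, 12500), 1)
    labeling <- detect_ils(h1)
    list(map = map, h1 = h1,
         h2 = track_harmonic(map, c(6500, 12500), 2, anchor = h1),
         h3 = track_harmonic(map, c(6500, 12500), 3, anchor = h1),
         labeling = labeling)
  })
}

fx_protocol_features <- function() {
  fx_cached("protocol_features",
            suppressMessages(extract_features(fx_protocol_sim()$recording)))
}

# small audio cohort with per-recording parameter spread (recovery suite)
fx_recovery_cohort <- function() {
  fx_cached("recovery_cohort", {
    spec <- cohort_spec(12, ar_prevalence = 0.25, seed = 202)
    sim <- simulate_cohort(spec)
    feats <- lapply(sim$recordings, function(r)
      suppressWarnings(suppressMessages(extract_features(r))))
    list(sim = sim, features = feats)
  })
}

# feature table with strongly separating planted features for selection tests
informative_stats <- function() {
  st <- feature_class_stats()
  st$mean_pos <- st$mean_neg
  st$sd_pos <- st$sd_neg
  shift <- c(amp_h1 = -2.2, rpm_ils = -2.2, ils_ampvar_h1 = 2.2)
  for (f in names(shift)) {
    i <- which(st$feature == f)
    st$mean_pos[i] <- st$mean_neg[i] + shift[[f]] * st$sd_neg[i]
  }
  st
}
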
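# Fluctuation spectra and the 19-feature acoustic catalogue.
#
# Feature semantics: "amplitude of frequency variation" / "amplitude of
# amplitude variation" is the amplitude of the dominant non-DC peak of the
# fluctuation spectrum of the tracked ridge component (units Hz for frequency
# tracks, a.u. for amplitude tracks). The search band's lower edge is three
# cycles per analysis window (3/T): an 8 s ILS window cannot resolve
# sub-0.4 Hz respiratory structure, so ILS variation features read the
# cardiac-rate modulation, while 30 s normal windows include the respiratory
# peak.

#' Names of the 19 acoustic features, in catalogue order
#'
#' Grouped as: normal operation (harmonic frequencies 1-3, frequency-variation
#' amplitudes 1-3, harmonic amplitudes 1-3, amplitude-variation amplitude of
#' harmonic 1, non-harmonic band amplitudes low/middle/high, rotational
#' speed), ILS operation (frequency-variation amplitude, amplitude-variation
#' amplitude, rotational speed), and physiologic rates (heart, respiratory).
#'
#' @return character vector of length 19.
#' @export
feature_names <- function() {
  c("freq_h1", "freq_h2", "freq_h3",
    "freqvar_h1", "freqvar_h2", "freqvar_h3",
    "amp_h1", "amp_h2", "amp_h3",
    "ampvar_h1",
    "nonharm_low", "nonharm_mid", "nonharm_high",
    "rpm_normal",
    "ils_freqvar_h1", "ils_ampvar_h1", "rpm_ils",
    "heart_rate", "resp_rate")
}

#' Feature catalogue with units and groups
#' @return data.frame with columns `feature`, `group`, `units`.
#' @export
feature_catalogue <- function() {
  data.frame(
    feature = feature_names(),
    group = c(rep("normal", 14), rep("ILS", 3), rep("physiologic", 2)),
    units = c("Hz", "Hz", "Hz", "Hz", "Hz", "Hz", "a.u.", "a.u.", "a.u.",
              "a.u.", "a.u.", "a.u.", "a.u.", "rpm", "Hz", "a.u.", "rpm",
              "bpm", "per minute"),
    stringsAsFactors = FALSE)
}

#' Fluctuation spectrum of a tracked ridge component
#'
#' Mean-detrended, Hann-windowed FFT amplitude spectrum of a uniformly sampled
#' track component (ridge frequency in Hz or ridge amplitude in a.u.),
#' zero-padded for fine peak interpolation and scaled so a pure sinusoidal
#' modulation with peak deviation `D` yields a spectral peak of amplitude `D`.
#' Gaps up to `max_gap_frac` are bridged linearly (with a message); more is an
#' error.
#'
#' @param values track component samples (may contain `NA` gaps).
#' @param time_step sample spacing in seconds.
#' @param max_freq upper frequency limit of the returned spectrum (Hz).
#' @param min_duration minimum window length in seconds (shorter input is an
#'   insufficient-data error; sub-0.1 Hz structure needs >= 10 s).
#' @param max_gap_frac largest tolerated gap fraction.
#' @param pad_factor zero-padding factor (removes scalloping of the peak
#'   amplitude estimate).
#' @return object of class `fluct_spectrum` with fields `frequencies` (from
#'   0 to `max_freq`), `amplitudes`, `window_sec`.
#' @export
fluctuation_spectrum <- function(values, time_step, max_freq = 5,
                                 min_duration = 10, max_gap_frac = 0.1,
                                 pad_factor = 8) {
  n <- length(values)
  if (n * time_step < min_duration)
    stop("insufficient data: window of ", round(n * time_step, 2),
         " s is shorter than ", min_duration, " s")
  gap_frac <- mean(is.na(values))
  if (gap_frac > max_gap_frac)
    stop("track has ", round(100 * gap_frac, 1), "% gaps (limit ",
         100 * max_gap_frac, "%)")
  if (gap_frac > 0) {
    message(sprintf("bridging %.1f%% track gaps linearly", 100 * gap_frac))
    values <- stats::approx(seq_len(n)[!is.na(values)], values[!is.na(values)],
                            xout = seq_len(n), rule = 2)$y
  }
  x <- values - mean(values)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))  # Hann
  n_pad <- pad_factor * n
  sp <- stats::fft(c(x * w, numeric(n_pad - n)))
  n_keep <- min(n_pad %/% 2, floor(max_freq * n_pad * time_step) + 1)
  amp <- 2 * Mod(sp[seq_len(n_keep)]) / sum(w)
  freqs <- (seq_len(n_keep) - 1) / (n_pad * time_step)
  structure(list(frequencies = freqs, amplitudes = amp,
                 window_sec = n * time_step),
            class = "fluct_spectrum")
}

#' @export
print.fluct_spectrum <- function(x, ...) {
  cat(sprintf("<fluct_spectrum> 0-%.2f Hz from a %.1f s window\n",
              max(x$frequencies), x$window_sec))
  invisible(x)
}

#' Dominant spectral peak of a fluctuation spectrum within a band
#'
#' @param fs a [fluctuation_spectrum()] result.
#' @param band `c(lo, hi)` search band in Hz.
#' @param prominence peak must exceed `prominence` times the median band
#'   amplitude to count as present.
#' @return list with `frequency`, `amplitude`, `present`.
#' @export
dominant_peak <- function(fs, band, prominence = 3) {
  sel <- which(fs$frequencies >= band[1] & fs$frequencies <= band[2])
  if (length(sel) < 3)
    return(list(frequency = NA_real_, amplitude = 0, present = FALSE))
  a <- fs$amplitudes[sel]
  i <- which.max(a)
  amp <- a[i]; frq <- fs$frequencies[sel[i]]
  if (i > 1 && i < length(a) && a[i - 1] > 0 && a[i + 1] > 0) {
    v <- .parabola_vertex(fs$frequencies[sel[i - 1]], log(a[i - 1]),
                          frq, log(amp),
                          fs$frequencies[sel[i + 1]], log(a[i + 1]))
    frq <- v[1]; amp <- exp(v[2])
  }
  present <- amp > 1e-9 && amp > prominence * stats::median(a)
  list(frequency = frq, amplitude = amp, present = present)
}

#' Extract the heart rate from a frequency-fluctuation spectrum
#'
#' The cardiac cycle frequency-modulates the fundamental, so the fluctuation
#' spectrum of the fundamental's frequency track (normal segments) carries a
#' strong peak at the heart rate — typically between 1 and 1.5 Hz. The search
#' band is widened to 0.7-3 Hz so tachycardic and bradycardic rates are not
#' clipped.
#'
#' @param fs a `fluct_spectrum` of the fundamental's frequency track.
#' @param band cardiac search band in Hz.
#' @param prominence peak-presence threshold (multiple of the median band
#'   amplitude).
#' @return heart rate in beats per minute, or `NA` when no sufficiently
#'   prominent peak exists.
#' @export
extract_heart_rate <- function(fs, band = c(0.7, 3), prominence = 3) {
  pk <- dominant_peak(fs, band, prominence)
  if (!pk$present) return(NA_real_)
  60 * pk$frequency
}

#' Extract the respiratory rate from an amplitude-fluctuation spectrum
#'
#' Respiration amplitude-modulates the pump sound, producing a strong peak
#' below 0.5 Hz in the fluctuation spectrum of the fundamental's amplitude
#' track (DC excluded).
#'
#' @param fs a `fluct_spectrum` of the fundamental's amplitude track.
#' @param band respiratory search band in Hz (lower edge excludes DC leakage).
#' @param prominence peak-presence threshold.
#' @return respiratory rate per minute, or `NA` when absent.
#' @export
extract_respiratory_rate <- function(fs, band = c(0.06, 0.5), prominence = 3) {
  band[1] <- max(band[1], 3 / fs$window_sec)
  pk <- dominant_peak(fs, band, prominence)
  if (!pk$present) return(NA_real_)
  60 * pk$frequency
}

#' Non-harmonic band amplitudes
#'
#' Mean map amplitude (a.u.) in the three bands defined by the recognizable
#' harmonic peaks — low: below the fundamental; middle: between the
#' fundamental and the second harmonic; high: above the second harmonic —
#' with each harmonic's neighborhood (+/- one channel FWHM) excised so peak
#' leakage does not count as noise, averaged over the given time windows.
#'
#' @param map a normalized `time_frequency_map`.
#' @param f1,f2 detected fundamental and second-harmonic frequencies (Hz).
#' @param windows data.frame of `start`, `end` time windows (normal-operation
#'   segments); `NULL` uses the full edge-trimmed extent.
#' @return named numeric `c(low, middle, high)` in a.u.; all `NA` when `f1`
#'   is undetected.
#' @export
band_amplitudes <- function(map, f1, f2 = 2 * f1, windows = NULL) {
  stopifnot(inherits(map, "time_frequency_map"))
  if (is.na(f1))
    return(c(low = NA_real_, middle = NA_real_, high = NA_real_))
  if (is.na(f2)) f2 <- 2 * f1
  fg <- map$frequencies
  excised <- rep(FALSE, length(fg))
  k <- 1
  while (k * f1 <= max(fg) + f1) {
    excised <- excised | abs(fg - k * f1) < (k * f1 / map$q)
    k <- k + 1
  }
  if (is.null(windows))
    windows <- data.frame(start = min(map$times) + map$edge_sec,
                          end = max(map$times) - map$edge_sec)
  tsel <- rep(FALSE, length(map$times))
  for (i in seq_len(nrow(windows)))
    tsel <- tsel | (map$times >= windows$start[i] & map$times <= windows$end[i])
  if (!any(tsel))
    return(c(low = NA_real_, middle = NA_real_, high = NA_real_))
  bandmean <- function(rows) {
    if (!any(rows)) return(NA_real_)
    mean(map$amplitudes[rows, tsel])
  }
  c(low = bandmean(fg < f1 & !excised),
    middle = bandmean(fg > f1 & fg < f2 & !excised),
    high = bandmean(fg > f2 & !excised))
}

#' Analysis configuration for feature extraction
#'
#' @param freq_grid scalogram frequency grid (Hz).
#' @param time_step scalogram hop in seconds.
#' @param q wavelet quality factor (channel FWHM = f / q).
#' @param rpm_range plausible fundamental rotational-speed range (rpm)
#'   spanning ILS through fast normal operation.
#' @param protocol ILS protocol `c(ils_rpm, duration, period)`.
#' @param normal_rpm_min lowest plausible normal rotational speed (rpm).
#' @param min_dwell,transition_pad ILS segmentation controls (s).
#' @param ils_interior_trim seconds trimmed from each end of an ILS segment
#'   before computing ILS statistics (keeps speed ramps out).
#' @param cardiac_band,resp_band physiologic search bands (Hz).
#' @param ils_min_duration minimum ILS analysis window (s); ILS fluctuation
#'   features are computed from a single 8 s window.
#' @param prominence peak-presence threshold for physiologic rates.
#' @return a named list of class `feature_config`.
#' @export
feature_config <- function(freq_grid = default_freq_grid(), time_step = 0.01,
                           q = 16.7, rpm_range = c(6500, 12500),
                           protocol = c(ils_rpm = 7000, duration = 8, period = 64),
                           normal_rpm_min = 8000, min_dwell = 2,
                           transition_pad = 0.5, ils_interior_trim = 0.6,
                           cardiac_band = c(0.7, 3), resp_band = c(0.06, 0.5),
                           ils_min_duration = 4, prominence = 3) {
  structure(list(freq_grid = freq_grid, time_step = time_step, q = q,
                 rpm_range = rpm_range, protocol = protocol,
                 normal_rpm_min = normal_rpm_min, min_dwell = min_dwell,
                 transition_pad = transition_pad,
                 ils_interior_trim = ils_interior_trim,
                 cardiac_band = cardiac_band, resp_band = resp_band,
                 ils_min_duration = ils_min_duration, prominence = prominence),
            class = "feature_config")
}

.extraction_failure <- function(recording_id, msg) {
  stop(structure(class = c("lvad_extraction_error", "error", "condition"),
                 list(message = paste0(recording_id, ": ", msg), call = NULL)))
}

# select track indices falling in any (start, end) window
.in_windows <- function(times, windows, trim = 0) {
  sel <- rep(FALSE, length(times))
  if (is.null(windows) || nrow(windows) == 0) return(sel)
  for (i in seq_len(nrow(windows)))
    sel <- sel | (times >= windows$start[i] + trim &
                    times <= windows$end[i] - trim)
  sel
}

# dominant-peak amplitude of a track component over one window; band lower
# edge at three cycles per window
.variation_amplitude <- function(values, time_step, window_sec, min_duration) {
  fs <- tryCatch(
    fluctuation_spectrum(values, time_step, min_duration = min_duration),
    error = function(e) NULL)
  if (is.null(fs)) return(NA_real_)
  pk <- dominant_peak(fs, c(3 / window_sec, 5), prominence = 0)
  pk$amplitude
}

#' Extract the 19 acoustic features from a recording
#'
#' Runs the full single-recording analysis: Gabor scalogram, amplitude
#' normalization to a.u., fundamental and harmonic ridge tracking, ILS
#' segmentation, fluctuation spectra, and the physiologic rates. Returns
#' exactly 19 features in catalogue order; features that cannot be computed
#' (e.g. the three ILS features when the recording contains no ILS window)
#' are explicitly flagged missing, never zero-filled. An unanalyzable
#' recording (no fundamental ridge) raises a structured
#' `lvad_extraction_error`.
#'
#' @param rec a [recording()] (>= 60 s preferred; shorter input warns).
#' @param config a [feature_config()].
#' @return an object of class `feature_vector`: fields `values` (named,
#'   length 19, `NA` where missing), `missing` (logical), `recording_id`,
#'   `ar_label`, `segments` (the ILS labeling).
#' @export
extract_features <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "lvad_recording"))
  if (rec_duration(rec) < 60)
    warning("recording shorter than 60 s; ILS window may be absent and ",
            "fluctuation resolution reduced")
  cfg <- config
  map <- gabor_scalogram(rec, freq_grid = cfg$freq_grid,
                         time_step = cfg$time_step, q = cfg$q)
  map <- tryCatch(normalize_amplitude(map),
                  error = function(e) .extraction_failure(rec$recording_id,
                                                          conditionMessage(e)))
  h1 <- track_harmonic(map, cfg$rpm_range, 1)
  if (mean(is.na(h1$frequency)) >= 0.5)
    .extraction_failure(rec$recording_id,
                        "no fundamental ridge found (>= 50% gaps)")
  labeling <- withCallingHandlers(
    detect_ils(h1, cfg$protocol, cfg$normal_rpm_min, cfg$min_dwell,
               cfg$transition_pad),
    warning = function(w) invokeRestart("muffleWarning"))
  h2 <- track_harmonic(map, cfg$rpm_range, 2, anchor = h1)
  h3 <- track_harmonic(map, cfg$rpm_range, 3, anchor = h1)

  tt <- map$times
  dt <- cfg$time_step
  analyzable <- c(min(tt) + map$edge_sec, max(tt) - map$edge_sec)
  norm_w <- segments_of(labeling, "normal")
  norm_w$start <- pmax(norm_w$start, analyzable[1])
  norm_w$end <- pmin(norm_w$end, analyzable[2])
  norm_w <- norm_w[norm_w$end > norm_w$start, , drop = FALSE]
  nsel <- .in_windows(tt, norm_w)
  if (!any(nsel))
    .extraction_failure(rec$recording_id, "no analyzable normal segment")

  v <- stats::setNames(rep(NA_real_, 19), feature_names())
  med <- function(x) stats::median(x, na.rm = TRUE)
  v["freq_h1"] <- med(h1$frequency[nsel])
  v["freq_h2"] <- med(h2$frequency[nsel])
  v["freq_h3"] <- med(h3$frequency[nsel])
  v["amp_h1"] <- med(h1$amplitude[nsel])
  v["amp_h2"] <- med(h2$amplitude[nsel])
  v["amp_h3"] <- med(h3$amplitude[nsel])
  v["rpm_normal"] <- hz_to_rpm(v[["freq_h1"]])

  # fluctuation features from the longest normal window
  lw <- norm_w[which.max(norm_w$end - norm_w$start), , drop = FALSE]
  lw_sec <- lw$end - lw$start
  lsel <- .in_windows(tt, lw)
  v["freqvar_h1"] <- .variation_amplitude(h1$frequency[lsel], dt, lw_sec, 10)
  v["freqvar_h2"] <- .variation_amplitude(h2$frequency[lsel], dt, lw_sec, 10)
  v["freqvar_h3"] <- .variation_amplitude(h3$frequency[lsel], dt, lw_sec, 10)
  v["ampvar_h1"] <- .variation_amplitude(h1$amplitude[lsel], dt, lw_sec, 10)

  ba <- band_amplitudes(map, v[["freq_h1"]], v[["freq_h2"]], windows = norm_w)
  v["nonharm_low"] <- ba[["low"]]
  v["nonharm_mid"] <- ba[["middle"]]
  v["nonharm_high"] <- ba[["high"]]

  ils_w <- segments_of(labeling, "ILS")
  if (nrow(ils_w) > 0) {
    isel <- .in_windows(tt, ils_w, trim = cfg$ils_interior_trim)
    if (any(isel)) v["rpm_ils"] <- hz_to_rpm(med(h1$frequency[isel]))
    li <- ils_w[which.max(ils_w$end - ils_w$start), , drop = FALSE]
    li$start <- li$start + cfg$ils_interior_trim
    li$end <- li$end - cfg$ils_interior_trim
    li_sec <- li$end - li$start
    lisel <- .in_windows(tt, li)
    if (li_sec >= cfg$ils_min_duration) {
      v["ils_freqvar_h1"] <- .variation_amplitude(h1$frequency[lisel], dt,
                                                  li_sec, cfg$ils_min_duration)
      v["ils_ampvar_h1"] <- .variation_amplitude(h1$amplitude[lisel], dt,
                                                 li_sec, cfg$ils_min_duration)
    }
  }

  fs_freq <- tryCatch(fluctuation_spectrum(h1$frequency[lsel], dt),
                      error = function(e) NULL)
  if (!is.null(fs_freq))
    v["heart_rate"] <- extract_heart_rate(fs_freq, cfg$cardiac_band,
                                          cfg$prominence)
  fs_amp <- tryCatch(fluctuation_spectrum(h1$amplitude[lsel], dt),
                     error = function(e) NULL)
  if (!is.null(fs_amp))
    v["resp_rate"] <- extract_respiratory_rate(fs_amp, cfg$resp_band,
                                               cfg$prominence)

  structure(list(values = v, missing = is.na(v),
                 recording_id = rec$recording_id, ar_label = rec$ar_label,
                 segments = labeling),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s: %d/19 features present\n",
              x$recording_id, sum(!x$missing)))
  df <- data.frame(feature = names(x$values), value = round(unname(x$values), 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  out <- as.data.frame(as.list(x$values))
  out <- cbind(data.frame(recording_id = x$recording_id), out,
               data.frame(ar_label = x$ar_label))
  out
}
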
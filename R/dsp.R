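# Time-frequency analysis.
#
# The scalogram is a constant-Q analytic Gabor filter bank: each channel is a
# Gaussian in the frequency domain centered on a grid frequency f with
# FWHM = f / 16.7 (about 10 Hz at 167 Hz, narrow enough to separate the
# fundamental from its cardiac-modulation sidebands while resolving sub-second
# amplitude fluctuations). Channels are evaluated from one large FFT of the
# signal followed by band-limited inverse FFTs (heterodyne decimation), so a
# two-minute recording is analyzed in a few seconds.

#' Default logarithmic frequency grid
#'
#' @param fmin,fmax grid limits in Hz (band of interest 20-2000 Hz).
#' @param bins_per_octave grid density.
#' @return numeric vector of grid frequencies.
#' @export
default_freq_grid <- function(fmin = 20, fmax = 2000, bins_per_octave = 48) {
  2^seq(log2(fmin), log2(fmax), by = 1 / bins_per_octave)
}

#' Band-limit a recording
#'
#' Zero-phase band-pass filtering in the frequency domain with raised-cosine
#' transition edges (stop-band attenuation far exceeds 40 dB, pass-band ripple
#' zero, length preserved). The recording band of interest is 20-2000 Hz.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz, `0 < low < high < sample_rate/2`.
#' @param transition fractional width of the raised-cosine edges (the lower
#'   transition spans `[low*(1-transition), low]`, the upper
#'   `[high, high*(1+transition)]`).
#' @return a band-limited [recording()] of identical length.
#' @export
bandlimit <- function(rec, low = 20, high = 2000, transition = 0.4) {
  stopifnot(inherits(rec, "lvad_recording"))
  fs <- rec$sample_rate
  if (low <= 0 || low >= high) stop("invalid band: need 0 < low < high")
  if (high >= fs / 2) stop("band outside Nyquist: high must be below sample_rate/2")
  x <- rec$samples
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency axis
  lo0 <- low * (1 - transition)
  hi1 <- high * (1 + transition)
  # raised-cosine edges: 0 below lo0, 1 above `low`; 1 below `high`, 0 above hi1
  gain <- .hann_step(f - (lo0 + low) / 2, low - lo0) *
    (1 - .hann_step(f - (high + hi1) / 2, hi1 - high))
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  recording(y, fs, recording_id = rec$recording_id, ar_label = rec$ar_label)
}

#' Gabor wavelet scalogram
#'
#' Computes an (unnormalized) time-frequency amplitude map of a recording with
#' an analytic Gabor filter bank on a frequency grid. Amplitudes are scaled so
#' a pure tone of waveform amplitude `A` at a grid frequency produces a ridge
#' of height `A`; at each time step the ridge profile across frequency is
#' Gaussian, which harmonic tracking exploits for sub-grid interpolation.
#'
#' The first and last `edge_sec(map)` seconds are within one wavelet support
#' half-width of the signal boundary and are excluded from downstream feature
#' statistics.
#'
#' @param rec a [recording()].
#' @param freq_grid frequency grid in Hz (default [default_freq_grid()]);
#'   must lie within (0, Nyquist).
#' @param time_step spacing of the output time grid in s.
#' @param q frequency-resolution quality factor: channel FWHM = f / q.
#' @return an object of class `time_frequency_map` with fields `times`,
#'   `frequencies`, `amplitudes` (frequency x time), `normalized`, `edge_sec`.
#' @export
gabor_scalogram <- function(rec, freq_grid = default_freq_grid(),
                            time_step = 0.01, q = 16.7) {
  stopifnot(inherits(rec, "lvad_recording"))
  if (length(freq_grid) == 0) stop("empty frequency grid")
  if (time_step <= 0) stop("time_step must be positive")
  fs <- rec$sample_rate
  if (any(freq_grid <= 0) || any(freq_grid >= fs / 2))
    stop("frequency grid must lie within (0, Nyquist)")
  freq_grid <- sort(freq_grid)
  x <- rec$samples
  n <- length(x)

  sigma_f <- (freq_grid / q) / (2 * sqrt(2 * log(2)))
  # intermediate channel rate: wide enough to hold the widest Gaussian
  r_target <- max(400, 10 * max(sigma_f))
  D <- max(2, round(fs / r_target))
  n_pad <- as.integer(ceiling(n / D) * D)
  m <- n_pad %/% D
  r_int <- fs / D
  df <- fs / n_pad
  X <- stats::fft(c(x, numeric(n_pad - n)))

  h <- max(1L, as.integer(round(time_step * r_int)))
  nf <- m %/% h
  if (nf < 1) stop("recording too short for the requested time_step")
  amp <- matrix(0, nrow = length(freq_grid), ncol = nf)
  half <- m %/% 2
  pos_max <- n_pad %/% 2  # last usable positive-frequency bin (1-based count)
  scale <- 2 / n_pad
  for (i in seq_along(freq_grid)) {
    f <- freq_grid[i]
    s <- as.integer(round(f / df)) + 1L - half
    s <- max(2L, min(s, pos_max - m + 1L))
    kk <- s:(s + m - 1L)
    fw <- (kk - 1) * df
    w <- exp(-0.5 * ((fw - f) / sigma_f[i])^2)
    y <- stats::fft(X[kk] * w, inverse = TRUE)
    a <- scale * Mod(y)
    amp[i, ] <- colMeans(matrix(a[seq_len(nf * h)], nrow = h))
  }
  times <- (seq_len(nf) - 0.5) * h / r_int
  structure(list(times = times, frequencies = freq_grid, amplitudes = amp,
                 normalized = FALSE,
                 edge_sec = 3 / (2 * pi * min(sigma_f)), q = q),
            class = "time_frequency_map")
}

#' @export
print.time_frequency_map <- function(x, ...) {
  cat(sprintf(paste0("<time_frequency_map> %d frequencies (%.1f-%.1f Hz) x ",
                     "%d times (%.2f-%.2f s), %s\n"),
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), min(x$times), max(x$times),
              if (x$normalized) "normalized (a.u., max = 100)" else "unnormalized"))
  invisible(x)
}

#' Edge-exclusion margin of a map
#' @param map a `time_frequency_map`.
#' @return seconds at each end of the map within one wavelet support
#'   half-width of the signal boundary.
#' @export
edge_sec <- function(map) map$edge_sec

#' Normalize a time-frequency map to arbitrary units
#'
#' Amplitudes are susceptible to recording conditions (e.g. stethoscope
#' placement), so they are expressed as a percentage of the largest amplitude
#' observed within a chosen time window (arbitrary units, a.u.). After
#' normalization the window maximum equals 100.
#'
#' @param map a `time_frequency_map`.
#' @param window `c(t0, t1)` normalization window in seconds; default is the
#'   full map extent minus the edge-exclusion margins.
#' @return the normalized map (normalizing again with the same window is a
#'   no-op).
#' @export
normalize_amplitude <- function(map, window = NULL) {
  stopifnot(inherits(map, "time_frequency_map"))
  if (is.null(window))
    window <- c(min(map$times) + map$edge_sec, max(map$times) - map$edge_sec)
  if (window[2] <= window[1])
    window <- range(map$times)  # degenerate margins on very short maps
  sel <- map$times >= window[1] & map$times <= window[2]
  if (!any(sel)) stop("normalization window contains no time steps")
  mx <- max(map$amplitudes[, sel])
  if (mx <= 0) stop("degenerate input: window maximum is zero, cannot normalize")
  map$amplitudes <- map$amplitudes * (100 / mx)
  map$normalized <- TRUE
  map$norm_window <- window
  map
}
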
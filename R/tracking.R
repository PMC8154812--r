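# Harmonic ridge tracking and intermittent-low-speed segmentation.

#' Convert rotational speed to acoustic frequency and back
#'
#' The impeller turning at `rpm` revolutions per minute produces its
#' fundamental spectral peak at `rpm / 60` Hz (10,000 rpm corresponds to a
#' 167 Hz peak; the normal 8000-12,000 rpm range maps to 133-200 Hz).
#'
#' @param rpm rotational speed in revolutions per minute (>= 0).
#' @param hz frequency in Hz (>= 0).
#' @return frequency in Hz, or rotational speed in rpm.
#' @export
rpm_to_hz <- function(rpm) {
  if (any(rpm < 0, na.rm = TRUE)) stop("rpm must be non-negative")
  rpm / 60
}

#' @rdname rpm_to_hz
#' @export
hz_to_rpm <- function(hz) {
  if (any(hz < 0, na.rm = TRUE)) stop("hz must be non-negative")
  hz * 60
}

#' Track a harmonic ridge through a time-frequency map
#'
#' At each time step the ridge frequency is the amplitude argmax within the
#' harmonic's search band (`harmonic_index` times the fundamental band implied
#' by `rpm_hint_range`), refined by parabolic interpolation of the
#' log-amplitude across the three neighboring grid channels (exact for the
#' Gaussian channel profile). The ridge amplitude is the interpolated map
#' value at the ridge. Time steps with no peak above the noise floor are
#' explicit gaps (`NA`), never silently interpolated.
#'
#' @param map a `time_frequency_map`.
#' @param rpm_hint_range `c(lo, hi)` plausible fundamental rotational speed in
#'   rpm; default spans ILS (7000 rpm) through fast normal operation.
#' @param harmonic_index 1, 2 or 3.
#' @param anchor optional `peak_track` of the fundamental on the same time
#'   grid; when given, the search band at each time step is
#'   `harmonic_index * anchor frequency * (1 +/- anchor_tol)`, which keeps
#'   higher harmonics from locking onto their neighbors.
#' @param band_pad widening of the static search band in Hz (per harmonic
#'   order), covering modulation excursions.
#' @param anchor_tol relative half-width of the anchored search band.
#' @param min_amplitude ridge amplitudes at or below this are marked as gaps.
#' @return an object of class `peak_track` with fields `times`, `frequency`,
#'   `amplitude`, `harmonic_index`.
#' @export
track_harmonic <- function(map, rpm_hint_range = c(6500, 12500),
                           harmonic_index = 1, anchor = NULL,
                           band_pad = 10, anchor_tol = 0.08,
                           min_amplitude = 1e-3) {
  stopifnot(inherits(map, "time_frequency_map"))
  k <- as.integer(harmonic_index)
  if (!k %in% 1:3) stop("harmonic_index must be 1, 2 or 3")
  f_lo <- k * rpm_to_hz(rpm_hint_range[1]) - k * band_pad
  f_hi <- k * rpm_to_hz(rpm_hint_range[2]) + k * band_pad
  rows <- which(map$frequencies >= f_lo & map$frequencies <= f_hi)
  if (length(rows) < 3) stop("search band covers fewer than 3 grid channels")
  A <- map$amplitudes[rows, , drop = FALSE]
  fg <- map$frequencies[rows]
  nt <- length(map$times)

  if (!is.null(anchor)) {
    stopifnot(inherits(anchor, "peak_track"),
              length(anchor$times) == nt)
    ctr <- k * anchor$frequency
    lo_t <- ctr * (1 - anchor_tol)
    hi_t <- ctr * (1 + anchor_tol)
    mask <- outer(fg, lo_t, ">=") & outer(fg, hi_t, "<=")
    mask[, is.na(ctr)] <- TRUE  # fall back to the static band at anchor gaps
    A <- ifelse(mask, A, -Inf)
  }

  idx <- max.col(t(A), ties.method = "first")
  peak_amp <- A[cbind(idx, seq_len(nt))]
  gap <- !is.finite(peak_amp) | peak_amp <= min_amplitude

  freq <- fg[idx]
  amp <- peak_amp
  # parabolic refinement on log amplitude where both neighbors are available
  ok <- which(!gap & idx > 1 & idx < length(fg))
  if (length(ok) > 0) {
    i0 <- idx[ok]
    a_l <- A[cbind(i0 - 1L, ok)]
    a_r <- A[cbind(i0 + 1L, ok)]
    a_c <- peak_amp[ok]
    usable <- is.finite(a_l) & is.finite(a_r) & a_l > 0 & a_r > 0
    for (j in which(usable)) {
      v <- .parabola_vertex(fg[i0[j] - 1L], log(a_l[j]),
                            fg[i0[j]], log(a_c[j]),
                            fg[i0[j] + 1L], log(a_r[j]))
      freq[ok[j]] <- v[1]
      amp[ok[j]] <- exp(v[2])
    }
  }
  freq[gap] <- NA_real_
  amp[gap] <- NA_real_
  structure(list(times = map$times, frequency = freq, amplitude = amp,
                 harmonic_index = k),
            class = "peak_track")
}

#' @export
print.peak_track <- function(x, ...) {
  cat(sprintf("<peak_track> harmonic %d: %d time steps, %.1f%% gaps, median %.1f Hz\n",
              x$harmonic_index, length(x$times),
              100 * mean(is.na(x$frequency)),
              stats::median(x$frequency, na.rm = TRUE)))
  invisible(x)
}

#' Segment a fundamental track into normal / ILS / transition operation
#'
#' Times where the tracked fundamental frequency sits below the midpoint
#' between the ILS protocol frequency (`ils_rpm / 60`) and the recording's
#' own normal-operation frequency (upper quartile of the track, floored at
#' `normal_rpm_min / 60`) for at least `min_dwell` seconds are labeled ILS. Each detected segment's boundaries are then refined to the
#' 50%-crossing between the segment's own plateau frequency and the
#' surrounding normal frequency, which makes the boundary estimate unbiased
#' with respect to the speed-ramp shape. Ramp intervals adjacent to ILS
#' segments are labeled `transition`; everything else is `normal`.
#'
#' A recording longer than one ILS period in which no ILS window is found
#' yields a warning and an all-normal labeling (real recordings may simply
#' miss the ILS window), not an error.
#'
#' @param track fundamental `peak_track` (fewer than 50% gaps).
#' @param protocol `c(ils_rpm, duration, period)` of the device's ILS
#'   protocol; defaults to 7000 rpm for 8 s every 64 s.
#' @param normal_rpm_min lowest plausible normal rotational speed (rpm).
#' @param min_dwell minimum time below threshold to count as ILS (s).
#' @param transition_pad ramp interval labeled `transition` on each side of an
#'   ILS segment (s).
#' @return an object of class `segment_labeling`: a data.frame with columns
#'   `start`, `end`, `kind` covering the track's extent, ordered and
#'   non-overlapping.
#' @export
detect_ils <- function(track, protocol = c(ils_rpm = 7000, duration = 8, period = 64),
                       normal_rpm_min = 8000, min_dwell = 2,
                       transition_pad = 0.5) {
  stopifnot(inherits(track, "peak_track"))
  f <- track$frequency
  tt <- track$times
  if (mean(is.na(f)) >= 0.5)
    stop("fundamental track has >= 50% gaps; cannot segment")
  dt <- stats::median(diff(tt))
  # detection threshold: midpoint between the protocol ILS frequency and the
  # recording's own normal-operation frequency (upper quartile of the track,
  # robust to the ~12% ILS duty cycle), floored at the configured minimum
  # normal speed. The device's commanded ILS speed is nominal; measured ILS
  # speeds scatter several hundred rpm around it, so a fixed midpoint against
  # normal_rpm_min would miss slow-drop recordings.
  normal_f <- max(stats::quantile(f, 0.75, na.rm = TRUE, names = FALSE),
                  rpm_to_hz(normal_rpm_min))
  thresh <- (rpm_to_hz(protocol[[1]]) + normal_f) / 2
  low <- !is.na(f) & f < thresh
  runs <- .runs_of(low)
  if (nrow(runs) > 0)
    runs <- runs[(runs[, 2] - runs[, 1] + 1) * dt >= min_dwell, , drop = FALSE]

  total_t <- tt[length(tt)] - tt[1]
  if (nrow(runs) == 0) {
    if (total_t > protocol[[3]])
      warning("no ILS window found in a recording longer than one ILS period; ",
              "returning all-normal labeling")
    seg <- data.frame(start = tt[1], end = tt[length(tt)], kind = "normal")
    return(structure(seg, class = c("segment_labeling", "data.frame")))
  }

  normal_level <- stats::median(f[!low], na.rm = TRUE)
  segs <- matrix(0, nrow(runs), 2)
  for (r in seq_len(nrow(runs))) {
    i1 <- runs[r, 1]; i2 <- runs[r, 2]
    ils_level <- stats::median(f[i1:i2], na.rm = TRUE)
    mid <- (ils_level + normal_level) / 2
    # onset: last index before i1 (within 3 s) still above mid
    j <- i1
    lim <- max(1, i1 - round(3 / dt))
    while (j > lim && !is.na(f[j - 1]) && f[j - 1] < mid) j <- j - 1
    if (j > 1 && !is.na(f[j - 1]) && !is.na(f[j]) && f[j - 1] >= mid) {
      frac <- (f[j - 1] - mid) / (f[j - 1] - f[j])
      t_on <- tt[j - 1] + frac * (tt[j] - tt[j - 1])
    } else t_on <- tt[j]
    # offset: symmetric on the trailing edge
    j <- i2
    lim <- min(length(f), i2 + round(3 / dt))
    while (j < lim && !is.na(f[j + 1]) && f[j + 1] < mid) j <- j + 1
    if (j < length(f) && !is.na(f[j + 1]) && !is.na(f[j]) && f[j + 1] >= mid) {
      frac <- (f[j + 1] - mid) / (f[j + 1] - f[j])
      t_off <- tt[j + 1] - frac * (tt[j + 1] - tt[j])
    } else t_off <- tt[j]
    segs[r, ] <- c(t_on, t_off)
  }

  # assemble the covering labeling
  t0 <- tt[1]; t1 <- tt[length(tt)]
  out <- data.frame(start = numeric(0), end = numeric(0), kind = character(0))
  cur <- t0
  for (r in seq_len(nrow(segs))) {
    a <- segs[r, 1]; b <- segs[r, 2]
    ta <- max(cur, a - transition_pad)
    if (ta > cur)
      out <- rbind(out, data.frame(start = cur, end = ta, kind = "normal"))
    if (a > ta)
      out <- rbind(out, data.frame(start = ta, end = a, kind = "transition"))
    out <- rbind(out, data.frame(start = a, end = b, kind = "ILS"))
    tb <- min(t1, b + transition_pad)
    if (tb > b)
      out <- rbind(out, data.frame(start = b, end = tb, kind = "transition"))
    cur <- tb
  }
  if (cur < t1)
    out <- rbind(out, data.frame(start = cur, end = t1, kind = "normal"))
  structure(out, class = c("segment_labeling", "data.frame"))
}

#' Extract segments of one kind from a labeling
#' @param labeling a `segment_labeling`.
#' @param kind one of `"normal"`, `"ILS"`, `"transition"`.
#' @return data.frame of `start`, `end` rows of that kind.
#' @export
segments_of <- function(labeling, kind) {
  labeling[labeling$kind == kind, c("start", "end"), drop = FALSE]
}
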
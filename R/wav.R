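#' Recording objects
#'
#' A `lvad_recording` holds a mono sound signal as sampled by an electronic
#' stethoscope on the chest wall above the pump: a numeric sample vector, the
#' sampling rate in Hz, an identifier, and an optional binary aortic
#' regurgitation label.
#'
#' @param samples numeric vector of (uncalibrated) sound-pressure samples.
#' @param sample_rate sampling rate in Hz.
#' @param recording_id character identifier.
#' @param ar_label optional 0/1 aortic-regurgitation label (`NA` if unknown).
#' @return an object of class `lvad_recording`.
#' @export
recording <- function(samples, sample_rate, recording_id = "rec", ar_label = NA) {
  if (!is.numeric(samples) || length(samples) < 1)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         recording_id = as.character(recording_id), ar_label = ar_label),
    class = "lvad_recording")
}

#' @export
print.lvad_recording <- function(x, ...) {
  cat(sprintf("<lvad_recording> %s: %.2f s at %g Hz (%d samples)",
              x$recording_id, length(x$samples) / x$sample_rate,
              x$sample_rate, length(x$samples)))
  if (!is.na(x$ar_label)) cat(sprintf(", AR label = %d", x$ar_label))
  cat("\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `lvad_recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$sample_rate

.wav_read_chunk_header <- function(con) {
  id <- readChar(con, 4, useBytes = TRUE)
  if (length(id) == 0 || nchar(id, type = "bytes") < 4) return(NULL)
  size <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(size) == 0) return(NULL)
  list(id = id, size = size)
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file containing 16-bit PCM or 32-bit IEEE-float samples.
#' Multi-channel files are reduced to their first channel with a warning.
#' 16-bit samples are scaled to `[-1, 1)` by dividing by 32768.
#'
#' @param path path to a `.wav` file.
#' @param recording_id identifier for the returned recording; defaults to the
#'   file basename without extension.
#' @return a [recording()].
#' @export
read_wav <- function(path, recording_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) < 44) stop("malformed WAV file (truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("malformed WAV file (no RIFF header): ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("malformed WAV file (no WAVE tag): ", path)

  fmt <- NULL; samples <- NULL
  repeat {
    hdr <- .wav_read_chunk_header(con)
    if (is.null(hdr)) break
    if (hdr$id == "fmt ") {
      raw_fmt <- readBin(con, "raw", n = hdr$size)
      if (length(raw_fmt) < 16) stop("malformed WAV file (short fmt chunk): ", path)
      u16 <- function(i) sum(as.integer(raw_fmt[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(raw_fmt[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      fmt <- list(code = u16(1), channels = u16(3), rate = u32(5), bits = u16(15))
    } else if (hdr$id == "data") {
      if (is.null(fmt)) stop("malformed WAV file (data before fmt): ", path)
      if (fmt$bits == 16 && fmt$code %in% c(1L, 65534L)) {
        n <- hdr$size %/% 2
        raw <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                       endian = "little")
        if (length(raw) < n) stop("malformed WAV file (truncated data): ", path)
        samples <- raw / 32768
      } else if (fmt$bits == 32 && fmt$code %in% c(3L, 65534L)) {
        n <- hdr$size %/% 4
        raw <- readBin(con, "double", n = n, size = 4, endian = "little")
        if (length(raw) < n) stop("malformed WAV file (truncated data): ", path)
        samples <- raw
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32): ", path)
      }
      break
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, where = hdr$size + hdr$size %% 2, origin = "current")
    }
  }
  if (is.null(samples) || length(samples) == 0)
    stop("malformed WAV file (no data chunk): ", path)
  if (fmt$channels > 1) {
    warning("multi-channel WAV; taking first channel: ", path)
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  }
  if (is.null(recording_id))
    recording_id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  recording(samples, fmt$rate, recording_id = recording_id)
}

#' Write a WAV file
#'
#' Writes mono (vector) or multi-channel (matrix, one column per channel)
#' audio as RIFF/WAVE, either 32-bit IEEE float (default, lossless for
#' analysis pipelines) or 16-bit PCM.
#'
#' @param x numeric vector, matrix, or a [recording()].
#' @param path output path.
#' @param sample_rate sampling rate in Hz (taken from `x` if a recording).
#' @param bits 32 (IEEE float) or 16 (PCM; samples clipped to `[-1, 1)`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = NULL, bits = 32) {
  if (inherits(x, "lvad_recording")) {
    sample_rate <- x$sample_rate
    x <- x$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  x <- as.matrix(x)
  nch <- ncol(x)
  inter <- as.numeric(t(x))  # interleave channels
  bytes_per <- bits / 8
  data_size <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  code <- if (bits == 32) 3L else 1L
  writeBin(code, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    q <- pmax(pmin(round(inter * 32768), 32767), -32768)
    writeBin(as.integer(q), con, size = 2, endian = "little")
  }
  invisible(path)
}
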
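# Minimal PCM-16 RIFF/WAVE reader and writer (mono), sufficient for the
# duty-cycled hydrophone recordings this package consumes.

#' Read / write 16-bit PCM WAV files
#'
#' `read_wav()` parses a mono (or first-channel) 16-bit PCM RIFF/WAVE file
#' and returns the raw integer samples plus the sampling rate; samples are
#' in the signed 16-bit range \[-32768, 32767\] and are NOT calibrated —
#' pass them through [calibrate()] to obtain pressure in micropascal.
#'
#' @param path WAV file path.
#' @return `read_wav()`: list with `samples` (integer vector) and `rate`
#'   (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop_invalid("not a WAVE file: ", path)
  }
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1L || bits != 16L) {
        stop_invalid("only 16-bit PCM WAV is supported")
      }
      extra <- size - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (padded)
    }
  }
  if (is.null(samples) || is.null(rate)) stop_invalid("malformed WAV: ", path)
  if (!is.null(channels) && channels > 1) {
    samples <- samples[seq(1, length(samples), by = channels)]
  }
  list(samples = samples, rate = rate)
}

#' @rdname read_wav
#' @param samples integer samples in \[-32768, 32767\].
#' @param rate sampling rate in Hz (default 44100).
#' @return `write_wav()`: `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 44100) {
  samples <- as.integer(round(samples))
  if (any(samples < -32768L | samples > 32767L)) {
    stop_invalid("samples clip the 16-bit range; lower the signal level")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_size <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}
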
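# Passive-acoustics pipeline: hydrophone calibration, per-second PSD and
# SPL, basal-noise estimation, boat-noise-peak flags, 12-min alignment.

#' Calibrate raw hydrophone samples to pressure
#'
#' Converts 16-bit integer samples to sound pressure in micropascal using
#' the hydrophone sensitivity, the recorder gain and its full-scale
#' voltage:
#' `pressure = raw/32768 * full_scale_volts / 10^((sensitivity + gain)/20)`.
#' There are no default calibration values: all three must be supplied.
#'
#' @param raw integer samples in the signed 16-bit range.
#' @param sensitivity hydrophone sensitivity in dB re 1 V/uPa (e.g. -170).
#' @param gain recorder gain in dB.
#' @param full_scale_volts voltage mapped to digital full scale.
#' @param rate sampling rate in Hz.
#' @param start recording start time (POSIXct UTC), optional.
#' @return An `audio_clip`: list with `pressure` (uPa), `rate`, `start`.
#' @export
calibrate <- function(raw, sensitivity, gain, full_scale_volts, rate = 44100,
                      start = NULL) {
  if (missing(sensitivity) || missing(gain) || missing(full_scale_volts)) {
    stop_invalid("calibration requires sensitivity, gain and full_scale_volts")
  }
  check_finite(c(sensitivity, gain, full_scale_volts), "calibration")
  if (any(abs(raw) > 32768)) stop_invalid("raw samples outside 16-bit range")
  pressure <- raw / 32768 * full_scale_volts / 10^((sensitivity + gain) / 20)
  audio_clip(pressure, rate = rate, start = start)
}

#' Calibrated audio clip
#'
#' @param pressure calibrated pressure samples in micropascal.
#' @param rate sampling rate in Hz (default 44100).
#' @param start recording start (POSIXct UTC) or NULL.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(pressure, rate = 44100, start = NULL) {
  if (rate <= 0) stop_invalid("rate must be > 0")
  structure(list(pressure = as.numeric(pressure), rate = rate, start = start),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("audio_clip: %.2f s at %d Hz\n",
              length(x$pressure) / x$rate, as.integer(x$rate)))
  invisible(x)
}

# split a clip into complete non-overlapping 1-s segments (partial tail
# dropped); returns a matrix rate x n_segments
segment_pressure <- function(clip, segment_s = 1) {
  seg_len <- as.integer(round(clip$rate * segment_s))
  n_seg <- length(clip$pressure) %/% seg_len
  if (n_seg < 1) stop_invalid("clip shorter than one segment")
  matrix(clip$pressure[seq_len(n_seg * seg_len)], nrow = seg_len)
}

#' Sound pressure level of a clip or per-second series
#'
#' `compute_spl()` returns `10 * log10(mean(p^2) / p_ref^2)` in dB re 1 uPa
#' (p_ref = 1 uPa) for a whole segment.  `spl_series()` applies it to each
#' complete non-overlapping 1-s segment of a clip.
#'
#' @param clip an [audio_clip()] (for `spl_series`) or numeric pressure
#'   vector in uPa (for `compute_spl`).
#' @param floor_db dB value returned (and flagged) for all-zero segments.
#' @return `compute_spl()`: scalar dB.  `spl_series()`: an `spl_series`
#'   data frame with columns `segment` (0-based), `spl`, plus attribute
#'   `start`.
#' @examples
#' compute_spl(rep(1, 1000))   # 0 dB re 1 uPa
#' compute_spl(rep(10, 1000))  # 20 dB
#' @export
compute_spl <- function(clip, floor_db = -120) {
  p <- if (inherits(clip, "audio_clip")) clip$pressure else as.numeric(clip)
  if (length(p) == 0) stop_invalid("empty segment")
  msp <- mean(p^2)
  if (msp == 0) {
    out <- floor_db
    attr(out, "silent") <- TRUE
    return(out)
  }
  10 * log10(msp)
}

#' @rdname compute_spl
#' @export
spl_series <- function(clip, floor_db = -120) {
  segs <- segment_pressure(clip)
  msp <- colMeans(segs^2)
  spl <- ifelse(msp > 0, 10 * log10(msp), floor_db)
  out <- data.frame(segment = seq_along(spl) - 1L, spl = spl)
  attr(out, "start") <- clip$start
  attr(out, "rate") <- clip$rate
  class(out) <- c("spl_series", "data.frame")
  out
}

#' Per-segment power spectral density
#'
#' Rectangular-windowed periodogram of each complete non-overlapping 1-s
#' segment, one-sided, in dB re 1 uPa^2/Hz over 0 to rate/2 (0-22.05 kHz
#' at the default rate).  The rectangular window makes Parseval exact: the
#' linear-scale PSD integrated over frequency equals the segment's mean
#' squared pressure.
#'
#' @param clip an [audio_clip()] of duration >= 1 s.
#' @param floor_db dB floor substituted for zero-power bins.
#' @return List with `freq` (Hz), `psd_db` (freq x segment matrix,
#'   dB re 1 uPa^2/Hz) and `psd_linear` (uPa^2/Hz).
#' @export
compute_psd <- function(clip, floor_db = -240) {
  segs <- segment_pressure(clip)
  n <- nrow(segs)
  fs <- clip$rate
  ft <- stats::mvfft(segs)
  # two-sided periodogram |X|^2/(fs*n), folded to one side
  two <- Mod(ft)^2 / (fs * n)
  half <- n %/% 2
  one <- two[1:(half + 1), , drop = FALSE]
  if (n %% 2 == 0) {
    if (half >= 2) one[2:half, ] <- 2 * one[2:half, ]
  } else {
    one[2:(half + 1), ] <- 2 * one[2:(half + 1), ]
  }
  freq <- (0:half) * fs / n
  psd_db <- ifelse(one > 0, 10 * log10(one), floor_db)
  list(freq = freq, psd_db = psd_db, psd_linear = one)
}

#' Basal ambient-noise level
#'
#' Estimates the constant background level present when no boats pass, as
#' a robust low quantile of the per-segment SPL distribution: the median
#' of the quietest fraction of segments (default: median of the lowest
#' 50%, i.e. the 25% quantile).
#'
#' @param spl an `spl_series` or numeric vector of per-segment SPL (dB).
#' @param quantile fraction of quietest segments whose median is taken
#'   (default 0.5).
#' @param min_segments minimum number of segments required (default 60).
#' @return Basal SPL in dB re 1 uPa.
#' @export
estimate_basal <- function(spl, quantile = 0.5, min_segments = 60L) {
  x <- if (is.data.frame(spl)) spl$spl else as.numeric(spl)
  if (length(x) < min_segments) {
    stop_invalid("need at least ", min_segments, " segments to estimate basal noise")
  }
  cut <- stats::quantile(x, quantile, names = FALSE, type = 7)
  stats::median(x[x <= cut])
}

#' Flag boat-noise peaks in an SPL series
#'
#' A segment is flagged as containing a motorboat noise peak when its mean
#' squared pressure is at least `factor` times the basal mean squared
#' pressure (ties flagged).  On the default linear pressure-squared scale
#' this is `SPL >= basal + 10*log10(factor)` dB (+2.55 dB at the default
#' factor 1.8); with `scale = "db"` the comparison is `SPL >= factor *
#' basal` directly in dB.
#'
#' @param spl an `spl_series` or numeric vector of per-segment SPL (dB).
#' @param basal basal SPL in dB (see [estimate_basal()]).
#' @param factor threshold ratio (> 1), default 1.8.
#' @param scale `"linear"` (ratio of mean squared pressures, default) or
#'   `"db"` (ratio of dB values).
#' @return Integer vector of 0/1 flags, one per segment.
#' @export
detect_noise_peaks <- function(spl, basal, factor = 1.8, scale = c("linear", "db")) {
  scale <- match.arg(scale)
  check_finite(basal, "basal")
  if (factor <= 1) stop_invalid("factor must be > 1")
  x <- if (is.data.frame(spl)) spl$spl else as.numeric(spl)
  threshold <- switch(scale,
                      linear = basal + 10 * log10(factor),
                      db = factor * basal)
  as.integer(x >= threshold)
}

#' Align per-segment noise flags to the model's time steps
#'
#' A step is flagged (noise = 1) iff at least one of its 1-s segments is
#' flagged.  Segments are placed on the step grid by their start time
#' relative to the grid origin.
#'
#' @param flags integer 0/1 per-segment flags.
#' @param segment_times segment start times: POSIXct, or numeric seconds
#'   from the grid origin.
#' @param origin grid origin (POSIXct, or 0 for numeric times).
#' @param step_duration step length in seconds (default 720).
#' @param n_steps number of steps in the grid (default: cover all
#'   segments).
#' @return A `noise_peak_series` data frame with columns `step`,
#'   `noise_flag`.
#' @export
align_noise_to_steps <- function(flags, segment_times, origin = 0,
                                 step_duration = 720, n_steps = NULL) {
  if (length(flags) != length(segment_times)) {
    stop_invalid("flags and segment_times must have equal length")
  }
  off <- if (inherits(segment_times, "POSIXt")) {
    as.numeric(difftime(as.POSIXct(segment_times, tz = "UTC"),
                        as.POSIXct(origin, tz = "UTC"), units = "secs"))
  } else {
    as.numeric(segment_times) - as.numeric(origin)
  }
  if (any(off < 0)) stop_invalid("segment before grid origin")
  idx <- floor(off / step_duration)
  if (is.null(n_steps)) n_steps <- if (length(idx)) max(idx) + 1 else 1
  if (length(idx) && max(idx) >= n_steps) stop_invalid("segment after grid end")
  step_flags <- integer(n_steps)
  hit <- unique(idx[flags == 1L]) + 1L
  step_flags[hit] <- 1L
  structure(data.frame(step = seq_len(n_steps) - 1L, noise_flag = step_flags),
            class = c("noise_peak_series", "data.frame"))
}

#' @rdname align_noise_to_steps
#' @param series a `noise_peak_series`.
#' @param path CSV path (`step,noise_flag`).
#' @export
write_noise_flags <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
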
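#' Receiver array
#'
#' @param ids receiver identifiers (unique).
#' @param x,y receiver coordinates in metres (local planar).
#' @return A `receiver_array` data frame with columns `receiver_id`, `x`, `y`.
#' @export
receiver_array <- function(ids, x, y) {
  if (anyDuplicated(ids)) stop_invalid("receiver ids must be unique")
  check_finite(c(x, y), "receiver coordinates")
  if (length(ids) != length(x) || length(x) != length(y)) {
    stop_invalid("ids, x, y must have equal length")
  }
  structure(data.frame(receiver_id = as.character(ids), x = x, y = y),
            class = c("receiver_array", "data.frame"))
}

#' @rdname receiver_array
#' @param path CSV path with header `receiver_id,x,y`.
#' @export
read_receivers <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("receiver_id", "x", "y") %in% names(d)))
  receiver_array(d$receiver_id, d$x, d$y)
}

#' @rdname receiver_array
#' @param receivers a `receiver_array`.
#' @export
write_receivers <- function(receivers, path) {
  write.csv(as.data.frame(receivers), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detection-model parameters
#'
#' The probability that a single tag emission is decoded by a receiver is a
#' logistic function of the fish-receiver distance, parametrised by the
#' inflection point `d50` (the distance at which detection probability is
#' exactly 0.5 — about 150 m for the receivers emulated here) and a
#' negative `slope` per metre.  Equivalently, with the logistic written as
#' `inverse-logit(alpha + beta * d)`, `alpha = -slope * d50` and
#' `beta = slope`; the (d50, slope) form is used because the prior is
#' naturally stated on the inflection point, which may legitimately be
#' negative for poorly-detecting receivers.
#'
#' @param d50 inflection-point distance in metres (may be negative).
#' @param slope logistic slope per metre; must be negative (detection decays
#'   with distance).
#' @param emissions_per_step number of tag emissions per time step (default
#'   6: one emission every 120 s within a 720-s step).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(d50 = 150, slope = -0.02, emissions_per_step = 6L) {
  check_finite(c(d50, slope), "detection parameters")
  if (slope >= 0) stop_invalid("slope must be negative")
  if (emissions_per_step < 1) stop_invalid("emissions_per_step must be >= 1")
  structure(list(d50 = d50, slope = slope,
                 emissions_per_step = as.integer(emissions_per_step)),
            class = "detection_params")
}

#' Detection probability at a given distance
#'
#' `inverse-logit(slope * (distance - d50))`: strictly decreasing in
#' distance, equal to 0.5 at the inflection point `d50`.
#'
#' @param distance fish-receiver distance(s) in metres, >= 0.
#' @param params a [detection_params()] object.
#' @return Detection probability in (0, 1), vectorised over `distance`.
#' @examples
#' detection_probability(150, detection_params(d50 = 150, slope = -0.02))
#' @export
detection_probability <- function(distance, params) {
  check_finite(distance, "distance")
  if (any(distance < 0)) stop_invalid("distance must be >= 0")
  plogis(params$slope * (distance - params$d50))
}

#' Simulate binomial detection counts along a track
#'
#' For each time step and receiver, the number of decoded emissions is
#' Binomial(`emissions_per_step`, `detection_probability(distance)`), with
#' detections conditionally independent across receivers and steps given
#' the fish positions.
#'
#' @param track a `fish_track` from [simulate_track()].
#' @param receivers a [receiver_array()].
#' @param params a [detection_params()] object.
#' @param seed integer seed.
#' @return A `detection_series`: integer matrix (steps x receivers) with
#'   receiver ids as column names and attributes `step_duration` and
#'   `emissions_per_step`.
#' @export
simulate_detections <- function(track, receivers, params, seed = 1L) {
  nr <- nrow(receivers)
  n <- nrow(track)
  dx <- outer(track$x, receivers$x, "-")
  dy <- outer(track$y, receivers$y, "-")
  pd <- plogis(params$slope * (sqrt(dx^2 + dy^2) - params$d50))
  set.seed(seed)
  counts <- matrix(rbinom(n * nr, size = params$emissions_per_step, prob = pd),
                   nrow = n, ncol = nr,
                   dimnames = list(NULL, receivers$receiver_id))
  mp <- attr(track, "params")
  detection_series(counts,
                   step_duration = if (is.null(mp)) 720 else mp$dt,
                   emissions_per_step = params$emissions_per_step)
}

#' Detection-count series container
#'
#' @param counts integer matrix, steps x receivers, with receiver ids as
#'   column names.
#' @param step_duration step length in seconds.
#' @param emissions_per_step maximum possible count per cell (number of tag
#'   emissions per step), or NA when unknown (binned field data).
#' @return A `detection_series` matrix.
#' @export
detection_series <- function(counts, step_duration = 720,
                             emissions_per_step = NA_integer_) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (!is.na(emissions_per_step) && any(counts > emissions_per_step)) {
    stop_invalid("counts exceed emissions_per_step")
  }
  storage.mode(counts) <- "integer"
  structure(counts, step_duration = step_duration,
            emissions_per_step = emissions_per_step,
            class = c("detection_series", "matrix", "array"))
}

#' @export
print.detection_series <- function(x, ...) {
  cat(sprintf("detection_series: %d steps x %d receivers, %d detections total\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @rdname detection_series
#' @param series a `detection_series`.
#' @param path CSV path; the long format `step,receiver_id,count` is used.
#' @export
write_detections <- function(series, path) {
  long <- data.frame(step = rep(seq_len(nrow(series)) - 1L, ncol(series)),
                     receiver_id = rep(colnames(series), each = nrow(series)),
                     count = as.vector(series))
  long <- long[order(long$step, long$receiver_id), ]
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname detection_series
#' @export
read_detections <- function(path, step_duration = 720,
                            emissions_per_step = NA_integer_) {
  d <- read.csv(path)
  stopifnot(all(c("step", "receiver_id", "count") %in% names(d)))
  ids <- sort(unique(as.character(d$receiver_id)))
  steps <- 0:max(d$step)
  counts <- matrix(0L, nrow = length(steps), ncol = length(ids),
                   dimnames = list(NULL, ids))
  counts[cbind(d$step + 1L, match(as.character(d$receiver_id), ids))] <-
    as.integer(d$count)
  detection_series(counts, step_duration, emissions_per_step)
}

#' Bin a raw detection log into fixed time steps
#'
#' Discretises tag detections into half-open bins
#' `[origin + n*step_duration, origin + (n+1)*step_duration)`, one column
#' per receiver.  The total count is conserved: every event lands in
#' exactly one bin.
#'
#' @param events data frame with columns `timestamp` (POSIXct, UTC),
#'   `tag_id`, `receiver_id`.
#' @param step_duration bin width in seconds (default 720).
#' @param origin POSIXct bin origin; must not be after the first event.
#' @param n_steps optional number of steps (default: enough to cover the
#'   last event).
#' @return A [detection_series()].
#' @export
bin_detections <- function(events, step_duration = 720, origin = NULL,
                           n_steps = NULL) {
  stopifnot(all(c("timestamp", "receiver_id") %in% names(events)))
  ts <- as.POSIXct(events$timestamp, tz = "UTC")
  if (is.null(origin)) {
    origin <- if (length(ts)) min(ts) else as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
  }
  origin <- as.POSIXct(origin, tz = "UTC")
  off <- as.numeric(difftime(ts, origin, units = "secs"))
  if (any(off < 0)) stop_invalid("event before bin origin")
  idx <- floor(off / step_duration)
  if (is.null(n_steps)) n_steps <- if (length(idx)) max(idx) + 1 else 1
  if (length(idx) && max(idx) >= n_steps) stop_invalid("event after last bin")
  ids <- sort(unique(as.character(events$receiver_id)))
  if (length(ids) == 0) ids <- "r1"
  counts <- matrix(0L, nrow = n_steps, ncol = length(ids),
                   dimnames = list(NULL, ids))
  if (length(idx)) {
    tab <- table(factor(idx, levels = 0:(n_steps - 1)),
                 factor(as.character(events$receiver_id), levels = ids))
    counts[] <- as.integer(tab)
  }
  out <- detection_series(counts, step_duration)
  attr(out, "origin") <- origin
  out
}

#' Classify timestamps as day or night
#'
#' A timestamp is daytime (1) iff `sunrise <= t < sunset` for its UTC date
#' (sunrise-inclusive, sunset-exclusive); otherwise night (0).
#'
#' @param timestamps POSIXct vector (UTC).
#' @param sun_table data frame with columns `date` (Date or yyyy-mm-dd
#'   string), `sunrise`, `sunset` (POSIXct UTC); must cover every date in
#'   `timestamps`.
#' @return Integer vector of 0/1 flags.
#' @export
classify_day_night <- function(timestamps, sun_table) {
  stopifnot(all(c("date", "sunrise", "sunset") %in% names(sun_table)))
  ts <- as.POSIXct(timestamps, tz = "UTC")
  dates <- as.Date(ts, tz = "UTC")
  i <- match(dates, as.Date(sun_table$date))
  if (anyNA(i)) {
    stop_invalid("sun_table does not cover date(s): ",
                 paste(unique(dates[is.na(i)]), collapse = ", "))
  }
  sr <- as.POSIXct(sun_table$sunrise, tz = "UTC")[i]
  ss <- as.POSIXct(sun_table$sunset, tz = "UTC")[i]
  as.integer(ts >= sr & ts < ss)
}
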
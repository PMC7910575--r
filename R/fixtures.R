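# Synthetic-data generation: the receiver geometry of the field study, the
# named behavioural scenarios, end-to-end datasets with ground truth, and
# calibrated WAV fixtures with injected boat-noise bursts.

#' Receiver grid of the study geometry
#'
#' A near-square grid of `n` receivers at the given spacing, centred at
#' the origin; the defaults reproduce the field layout of 14 receivers on
#' a 150 x 150 m lattice.
#'
#' @param n number of receivers (>= 1).
#' @param spacing grid pitch in metres.
#' @return A [receiver_array()].
#' @examples
#' make_receiver_grid(14, 150)
#' @export
make_receiver_grid <- function(n = 14L, spacing = 150) {
  if (n < 1) stop_invalid("n must be >= 1")
  rows <- max(1L, as.integer(round(sqrt(n))))
  cols <- as.integer(ceiling(n / rows))
  gx <- (seq_len(cols) - (cols + 1) / 2) * spacing
  gy <- (seq_len(rows) - (rows + 1) / 2) * spacing
  grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  receiver_array(sprintf("r%02d", seq_len(n)), grid$x, grid$y)
}

#' Named simulation scenarios
#'
#' Bundles movement, switching, detection and run-length settings.  The
#' three named behavioural regimes differ only in the switching
#' probabilities, applied identically in all four covariate cells:
#' `shy` fish tend to remain hidden (p = 0.2, q = 0.95), `intermediate`
#' fish have no preference (p = q = 0.5), and `bold` fish tend to keep
#' swimming (p = 0.95, q = 0.2).  These values are illustrative defaults
#' for the qualitative regimes, not field estimates.
#'
#' @param name one of `"shy"`, `"intermediate"`, `"bold"`, `"custom"`.
#' @param movement a [movement_params()]; default: centre (20, -15) m,
#'   k = 5e-4 per second, radius = 100 m, dt = 720 s.
#' @param transition a [transition_params()]; defaults per `name`
#'   (required for `"custom"`).
#' @param detection a [detection_params()].
#' @param n_steps number of 12-min steps (default 1000).
#' @param seed integer seed.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name = c("intermediate", "shy", "bold", "custom"),
                     movement = movement_params(20, -15, 5e-4, 100),
                     transition = NULL,
                     detection = detection_params(),
                     n_steps = 1000L, seed = 1L) {
  name <- match.arg(name)
  if (is.null(transition)) {
    pq <- switch(name,
                 shy = c(0.2, 0.95),
                 intermediate = c(0.5, 0.5),
                 bold = c(0.95, 0.2),
                 custom = stop_invalid("custom scenario needs a transition argument"))
    m <- transition_matrix(pq[1], pq[2])
    transition <- transition_params(m, m, m, m)
  }
  structure(list(name = name, movement = movement, transition = transition,
                 detection = detection, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "scenario")
}

# diel + boat-traffic covariates: 12-hour day/night blocks (60 steps of
# 12 min each), boat-noise presence more likely by day than by night
simulate_covariates <- function(n_steps, seed, p_noise_day = 0.15,
                                p_noise_night = 0.05) {
  daylight <- rep(rep(c(1L, 0L), each = 60L), length.out = n_steps)
  set.seed(seed)
  noise <- ifelse(runif(n_steps) < ifelse(daylight == 1, p_noise_day,
                                          p_noise_night), 1L, 0L)
  covariate_series(daylight, noise)
}

#' End-to-end synthetic dataset with ground truth
#'
#' Simulates covariates, the behavioural state chain, the movement track
#' and the binomial detection counts for a scenario observed by a
#' receiver array, and returns them together with the generating
#' parameter values keyed by the fitter's parameter names (so recovery
#' experiments can join posterior summaries to truth).
#'
#' @param scen a [scenario()].
#' @param receivers a [receiver_array()]; default the 14-receiver 150-m
#'   grid.
#' @return List with `track`, `detections`, `covariates`, `states`,
#'   `receivers` and `truth` (named numeric vector).
#' @export
make_dataset <- function(scen = scenario(), receivers = make_receiver_grid()) {
  seed <- scen$seed
  covariates <- simulate_covariates(scen$n_steps, seed + 1L)
  states <- simulate_states(scen$transition, covariates, init = STATE_SWIMMING,
                            seed = seed + 2L)
  start <- c(scen$movement$hr_x, scen$movement$hr_y)
  track <- simulate_track(scen$movement, states, start = start,
                          seed = seed + 3L)
  detections <- simulate_detections(track, receivers, scen$detection,
                                    seed = seed + 4L)
  truth <- c(scen$movement$hr_x, scen$movement$hr_y, scen$movement$k,
             scen$movement$radius, scen$detection$d50, scen$detection$slope,
             unlist(lapply(CELL_NAMES, function(cl) {
               c(scen$transition[[cl]][1, 1], scen$transition[[cl]][2, 2])
             })))
  names(truth) <- PARAM_NAMES
  list(track = track, detections = detections, covariates = covariates,
       states = states, receivers = receivers, truth = truth)
}

#' Synthetic boat-noise WAV fixture
#'
#' Writes a calibrated 16-bit PCM WAV of Gaussian background noise at a
#' given basal SPL with band-limited (50 Hz - 10 kHz) broadband bursts
#' injected at stated excesses over the basal mean squared pressure, plus
#' the per-second truth labels.  Event starts and durations are in whole
#' seconds so labels are unambiguous.  The fixed calibration (sensitivity
#' -170 dB re 1 V/uPa, gain 0 dB, full scale 1 V) is returned so the
#' detector can invert it.
#'
#' @param path output WAV path.
#' @param duration total duration in seconds.
#' @param basal_spl background level in dB re 1 uPa (default 120).
#' @param events data frame with columns `start` (s), `duration` (s),
#'   `excess_db` (total SPL excess over basal during the event).
#' @param rate sampling rate (default 44100).
#' @param seed integer seed.
#' @return List with `path`, `labels` (data frame `second`, `flagged`),
#'   `calibration`, `basal_spl`.
#' @export
make_boat_wav <- function(path, duration = 60, basal_spl = 120,
                          events = data.frame(start = numeric(),
                                              duration = numeric(),
                                              excess_db = numeric()),
                          rate = 44100, seed = 1L) {
  if (nrow(events) > 0) {
    if (any(events$start != round(events$start)) ||
        any(events$duration != round(events$duration))) {
      stop_invalid("event start and duration must be whole seconds")
    }
    if (any(events$start < 0 | events$start + events$duration > duration)) {
      stop_invalid("events must lie within the clip duration")
    }
  }
  set.seed(seed)
  n <- as.integer(duration * rate)
  basal_rms <- 10^(basal_spl / 20)        # uPa
  pressure <- rnorm(n, 0, basal_rms)
  labels <- integer(duration)
  for (i in seq_len(nrow(events))) {
    a <- events$start[i]; d <- events$duration[i]
    idx <- (a * rate + 1):((a + d) * rate)
    burst_msp <- basal_rms^2 * (10^(events$excess_db[i] / 10) - 1)
    pressure[idx] <- pressure[idx] +
      bandlimited_noise(length(idx), rate, 50, 10000, sqrt(burst_msp))
    labels[(a + 1):(a + d)] <- 1L
  }
  calibration <- list(sensitivity = -170, gain = 0, full_scale_volts = 1)
  upa_per_count <- calibration$full_scale_volts /
    10^((calibration$sensitivity + calibration$gain) / 20) / 32768
  raw <- round(pressure / upa_per_count)
  if (any(abs(raw) > 32767)) {
    stop_invalid("signal clips 16-bit full scale; lower basal_spl or excesses")
  }
  write_wav(raw, path, rate)
  list(path = path,
       labels = data.frame(second = seq_len(duration) - 1L, flagged = labels),
       calibration = calibration, basal_spl = basal_spl)
}

# zero-phase band-limited Gaussian noise with a target RMS
bandlimited_noise <- function(n, rate, f_lo, f_hi, rms) {
  x <- rnorm(n)
  ft <- fft(x)
  freq <- (seq_len(n) - 1) * rate / n
  freq <- pmin(freq, rate - freq)  # mirror for the negative half
  ft[freq < f_lo | freq > f_hi] <- 0
  y <- Re(fft(ft, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}
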
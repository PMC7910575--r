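#' Movement (biased random walk) parameters
#'
#' Bundles the home-range parameters of the biased-random-walk (BRW)
#' movement process: the attraction centre, the strength `k` of the drift
#' pulling the fish back towards it, and the home-range `radius`.  The walk
#' is a discrete-time Ornstein-Uhlenbeck process,
#' \deqn{x_n = x_{n-1} + k\,\Delta t\,(c - x_{n-1}) + \epsilon_n,\qquad
#'       \epsilon_n \sim N(0, \sigma^2 \Delta t),}
#' independently per axis, with the innovation variance calibrated so that
#' `radius` is the 95% quantile of the stationary distance to the centre
#' (\eqn{\sigma^2 \Delta t = (1 - (1 - k \Delta t)^2)\,\mathrm{radius}^2 /
#' \chi^2_{0.95}(2)}, the discrete-time analogue of the continuous OU
#' calibration \eqn{\sigma^2 = 2 k\,\mathrm{radius}^2 / \chi^2_{0.95}(2)}).
#'
#' @param hr_x,hr_y home-range centre coordinates (metres, local planar).
#' @param k attraction strength towards the centre (per second, >= 0).
#' @param radius home-range radius (metres, > 0): the 95% quantile of the
#'   stationary distance to the centre.
#' @param dt time-step length in seconds (default 720 s, the 12-min step
#'   imposed by the duty-cycled noise recordings).
#' @return An object of class `movement_params`.
#' @examples
#' movement_params(0, 0, k = 5e-4, radius = 100)
#' @export
movement_params <- function(hr_x, hr_y, k, radius, dt = 720) {
  check_finite(c(hr_x, hr_y, k, radius, dt), "movement parameters")
  if (k < 0) stop_invalid("k must be >= 0")
  if (radius <= 0) stop_invalid("radius must be > 0")
  if (dt <= 0) stop_invalid("dt must be > 0")
  structure(list(hr_x = hr_x, hr_y = hr_y, k = k, radius = radius, dt = dt),
            class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat(sprintf(
    "BRW movement: centre (%.1f, %.1f) m, k = %.3g s^-1, radius = %.1f m, dt = %.0f s\n",
    x$hr_x, x$hr_y, x$k, x$radius, x$dt))
  invisible(x)
}

# per-axis innovation variance over one step, calibrated so that the
# DISCRETE chain's stationary per-axis variance is radius^2/chisq and
# hence `radius` is the exact 95% quantile of the stationary distance to
# the centre: sigma^2*dt = (1 - (1 - k*dt)^2) * radius^2 / chisq.
# For k*dt -> 0 this reduces to the continuous-time OU calibration
# sigma^2 = 2*k*radius^2/chisq.
brw_step_var <- function(params) {
  kdt <- params$k * params$dt
  kdt * (2 - kdt) * params$radius^2 / CHI2_95_2DF
}

# per-axis stationary variance of the continuous-time OU limit
brw_stationary_var <- function(params) {
  params$radius^2 / CHI2_95_2DF
}

#' One step of the two-state movement process
#'
#' Advances the position by one time step.  In the hidden state the fish
#' does not move and the previous position is returned exactly; in the
#' swimming state the position follows the discrete OU step described in
#' [movement_params()].
#'
#' @param prev numeric length-2 vector, previous position (x, y) in metres.
#' @param params a [movement_params()] object.
#' @param state behavioural state: 1 (swimming) or 2 (hidden).
#' @return Numeric length-2 vector, the new position.
#' @details The Euler discretisation requires `k * dt < 1`; larger values
#'   make the deterministic part of the update overshoot the centre and the
#'   walk diverge, so they are rejected with an error.
#' @examples
#' p <- movement_params(100, 0, k = 5e-4, radius = 100)
#' brw_step(c(10, 20), p, state = 2)  # hidden: unchanged
#' @export
brw_step <- function(prev, params, state) {
  check_finite(prev, "prev")
  if (length(prev) != 2) stop_invalid("prev must be a length-2 (x, y) vector")
  if (!state %in% c(STATE_SWIMMING, STATE_HIDDEN)) {
    stop_invalid("state must be 1 (swimming) or 2 (hidden)")
  }
  if (state == STATE_HIDDEN) return(prev)
  kdt <- params$k * params$dt
  if (kdt >= 1) {
    stop_invalid("k * dt = ", format(kdt),
                 " >= 1: unstable discretisation, reduce k or dt")
  }
  centre <- c(params$hr_x, params$hr_y)
  drift <- prev + kdt * (centre - prev)
  drift + rnorm(2L, mean = 0, sd = sqrt(brw_step_var(params)))
}

#' Simulate a full movement track for a given state sequence
#'
#' Runs the two-state movement process over a supplied sequence of
#' behavioural states.  Whenever the state is hidden the position is carried
#' over unchanged; whenever it is swimming a BRW step is taken.
#'
#' @param params a [movement_params()] object.
#' @param states integer vector of behavioural states (1 swimming,
#'   2 hidden), one per time step.
#' @param start numeric length-2 start position; used as the position of
#'   step 1 regardless of its state.
#' @param seed integer seed; the track is reproducible given the seed.
#' @return A `fish_track`: data frame with columns `step` (0-based), `x`,
#'   `y`, `state`, carrying `params` and `seed` as attributes.
#' @examples
#' p <- movement_params(0, 0, k = 5e-4, radius = 100)
#' trk <- simulate_track(p, states = rep(1L, 100), start = c(0, 0), seed = 1)
#' head(trk)
#' @export
simulate_track <- function(params, states, start = c(params$hr_x, params$hr_y),
                           seed = 1L) {
  if (length(states) == 0) stop_invalid("states must be non-empty")
  if (!all(states %in% c(STATE_SWIMMING, STATE_HIDDEN))) {
    stop_invalid("states must contain only 1 (swimming) and 2 (hidden)")
  }
  check_finite(start, "start")
  n <- length(states)
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  pos[1, ] <- start
  set.seed(seed)
  if (n > 1) {
    for (i in 2:n) pos[i, ] <- brw_step(pos[i - 1, ], params, states[i])
  }
  track <- data.frame(step = seq_len(n) - 1L, x = pos[, 1], y = pos[, 2],
                      state = as.integer(states))
  attr(track, "params") <- params
  attr(track, "seed") <- seed
  class(track) <- c("fish_track", "data.frame")
  track
}

#' @export
print.fish_track <- function(x, ...) {
  cat(sprintf("fish_track: %d steps, %.1f%% hidden\n", nrow(x),
              100 * mean(x$state == STATE_HIDDEN)))
  NextMethod()
}

#' Write / read a track as columnar text
#'
#' The track itself goes to `path` as CSV with header `step,x,y,state`; the
#' movement parameters and seed go to a JSON sidecar `<path>.json`.
#'
#' @param track a `fish_track` from [simulate_track()].
#' @param path output CSV path.
#' @return `write_track()` returns `path` invisibly; `read_track()` returns
#'   the `fish_track` (with parameters restored from the sidecar when it
#'   exists).
#' @export
write_track <- function(track, path) {
  write.csv(as.data.frame(track)[, c("step", "x", "y", "state")], path,
            row.names = FALSE, quote = FALSE)
  p <- attr(track, "params")
  meta <- list(seed = attr(track, "seed"))
  if (!is.null(p)) meta$params <- unclass(p)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  track <- read.csv(path)
  stopifnot(all(c("step", "x", "y", "state") %in% names(track)))
  track$state <- as.integer(track$state)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$params)) {
      attr(track, "params") <- do.call(movement_params, as.list(meta$params))
    }
    attr(track, "seed") <- meta$seed
  }
  class(track) <- c("fish_track", "data.frame")
  track
}
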
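# Bayesian inference for the two-state SSM: reference R implementations of
# the joint density and the state-marginalised likelihood (used for
# validation), the Rcpp Metropolis-within-Gibbs driver, and diagnostics.

# parameter order shared with the C++ sampler
PARAM_NAMES <- c("hr_x", "hr_y", "k", "radius", "d50", "slope",
                 "p_day_noise", "q_day_noise",
                 "p_day_silence", "q_day_silence",
                 "p_night_noise", "q_night_noise",
                 "p_night_silence", "q_night_silence")

# the 12 biological scalars (detection curve excluded)
MOVEMENT_PARAM_NAMES <- setdiff(PARAM_NAMES, c("d50", "slope"))

# covariate cell order shared with the C++ sampler
CELL_NAMES <- c("day_noise", "day_silence", "night_noise", "night_silence")

cell_index <- function(daylight, noise) {
  ifelse(daylight == 1, 0L, 2L) + ifelse(noise == 1, 0L, 1L)
}

# log transition probability from state a to state b (1/2 coding) under
# the (p, q) pair of a cell
log_transition <- function(a, b, p, q) {
  m <- matrix(c(p, 1 - q, 1 - p, q), nrow = 2)
  log(m[a, b])
}

#' Joint log posterior density of the state-space model
#'
#' Evaluates, up to nothing (all normalising constants included), the log
#' of prior x state-chain x movement x detection likelihood for a complete
#' configuration of parameters and latent track.  Parameters are taken at
#' the sampler's coordinates where transformed (`k` and `slope` are
#' supplied naturally; their log-scale Jacobians are included, matching
#' the MCMC target).  Returns `-Inf` (never errors) on any support
#' violation: parameters outside their priors, `k * dt >= 1`, or a hidden
#' step whose position moved.
#'
#' @param track a `fish_track` (positions + states).
#' @param params named list with `hr_x`, `hr_y`, `k`, `radius`, `d50`,
#'   `slope` and `transition` (a [transition_params()]).
#' @param counts a [detection_series()] (steps x receivers).
#' @param covariates a [covariate_series()].
#' @param receivers a [receiver_array()].
#' @param priors an [default_priors()] object.
#' @param centre0 detection-weighted receiver centroid anchoring the
#'   centre prior (default: computed from `counts` and `receivers`).
#' @param emissions_per_step binomial trials per step.
#' @param dt step duration (s).
#' @return Scalar log density.
#' @export
joint_log_density <- function(track, params, counts, covariates, receivers,
                              priors = default_priors(),
                              centre0 = detection_centroid(counts, receivers),
                              emissions_per_step = 6L, dt = 720) {
  n <- nrow(track)
  stopifnot(nrow(counts) == n, nrow(covariates) == n)
  tp <- params$transition
  pq <- unlist(lapply(CELL_NAMES, function(cl) {
    c(tp[[cl]][1, 1], tp[[cl]][2, 2])
  }))
  eta <- qlogis(pq)
  lp <- log_prior(params$hr_x, params$hr_y, log(params$k), params$radius,
                  params$d50, log(-params$slope), eta, priors, centre0, dt)
  if (!is.finite(lp)) return(-Inf)

  mp <- movement_params(params$hr_x, params$hr_y, params$k, params$radius, dt)
  sv <- brw_step_var(mp)        # per-axis step variance
  v1 <- brw_stationary_var(mp)  # per-axis initial variance

  # initial state (uniform over the two states) and initial position
  ll <- log(0.5) +
    dnorm(track$x[1], params$hr_x, sqrt(v1), log = TRUE) +
    dnorm(track$y[1], params$hr_y, sqrt(v1), log = TRUE)

  kdt <- params$k * dt
  if (n > 1) {
    for (i in 2:n) {
      cl <- CELL_NAMES[cell_index(covariates$daylight[i],
                                  covariates$noise[i]) + 1L]
      ll <- ll + log_transition(track$state[i - 1], track$state[i],
                                tp[[cl]][1, 1], tp[[cl]][2, 2])
      if (track$state[i] == STATE_HIDDEN) {
        if (track$x[i] != track$x[i - 1] || track$y[i] != track$y[i - 1]) {
          return(-Inf)
        }
      } else {
        mx <- track$x[i - 1] + kdt * (params$hr_x - track$x[i - 1])
        my <- track$y[i - 1] + kdt * (params$hr_y - track$y[i - 1])
        ll <- ll + dnorm(track$x[i], mx, sqrt(sv), log = TRUE) +
          dnorm(track$y[i], my, sqrt(sv), log = TRUE)
      }
      if (!is.finite(ll)) return(-Inf)
    }
  }

  dx <- outer(track$x, receivers$x, "-")
  dy <- outer(track$y, receivers$y, "-")
  pd <- plogis(params$slope * (sqrt(dx^2 + dy^2) - params$d50))
  ll <- ll + sum(dbinom(unclass(counts), emissions_per_step, pd, log = TRUE))
  lp + ll
}

#' State-marginalised movement log likelihood (forward algorithm)
#'
#' Given a fixed position sequence, sums the movement x switching density
#' over all 2^N behavioural state sequences with the forward algorithm.
#' A hidden step requires exactly zero displacement (its contribution is
#' an indicator); a swimming step contributes the BRW transition density.
#' The first step contributes only the initial state weights (no position
#' density), so the positions are treated as given.
#'
#' @param positions two-column matrix (x, y) of positions, one row per
#'   step.
#' @param transition a [transition_params()].
#' @param covariates a [covariate_series()] of matching length.
#' @param movement a [movement_params()].
#' @param init_dist initial state distribution, default `c(0.5, 0.5)`;
#'   use `c(1, 0)` to condition on starting in the swimming state.
#' @return Scalar log probability (log density).
#' @export
forward_state_loglik <- function(positions, transition, covariates, movement,
                                 init_dist = c(0.5, 0.5)) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n >= 1, nrow(covariates) == n)
  sv <- brw_step_var(movement)
  kdt <- movement$k * movement$dt
  lalpha <- log(init_dist)  # log forward weights over (swimming, hidden)
  if (n > 1) {
    for (i in 2:n) {
      cl <- CELL_NAMES[cell_index(covariates$daylight[i],
                                  covariates$noise[i]) + 1L]
      p <- transition[[cl]][1, 1]
      q <- transition[[cl]][2, 2]
      lT <- log(matrix(c(p, 1 - q, 1 - p, q), nrow = 2))
      mx <- positions[i - 1, 1] + kdt * (movement$hr_x - positions[i - 1, 1])
      my <- positions[i - 1, 2] + kdt * (movement$hr_y - positions[i - 1, 2])
      lswim <- dnorm(positions[i, 1], mx, sqrt(sv), log = TRUE) +
        dnorm(positions[i, 2], my, sqrt(sv), log = TRUE)
      lhide <- if (all(positions[i, ] == positions[i - 1, ])) 0 else -Inf
      lemit <- c(lswim, lhide)
      new <- vapply(1:2, function(b) {
        logsumexp(lalpha + lT[, b]) + lemit[b]
      }, numeric(1))
      lalpha <- new
    }
  }
  logsumexp(lalpha)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Detection-weighted receiver centroid
#'
#' The receiver positions averaged with weights equal to each receiver's
#' total detection count; anchors the home-range-centre prior and the
#' sampler initialisation.
#'
#' @param counts a [detection_series()].
#' @param receivers a [receiver_array()].
#' @return Numeric length-2 (x, y).
#' @export
detection_centroid <- function(counts, receivers) {
  w <- colSums(unclass(counts))
  if (sum(w) == 0) w <- rep(1, length(w))
  c(sum(w * receivers$x), sum(w * receivers$y)) / sum(w)
}

#' Fit the state-space model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler over the model parameters (home
#' range centre, `k`, `radius`, detection `d50` and `slope`, and the 8
#' switching probabilities) and the latent track (positions and
#' behavioural states).  Continuous parameters and latent positions move
#' by random-walk proposals (scales adapted during burn-in only); each
#' latent state is updated by a joint state+position flip whose position
#' proposal is the BRW forward density, so hidden steps keep exact
#' position equality.
#'
#' @param counts a [detection_series()] (steps x receivers).
#' @param receivers a [receiver_array()].
#' @param covariates a [covariate_series()] of matching length.
#' @param priors an [default_priors()] object.
#' @param config an [mcmc_config()].
#' @param emissions_per_step binomial trials per step (default 6).
#' @param dt step duration in seconds (default 720).
#' @param prior_only if TRUE the detection likelihood is dropped
#'   (zero-information data): posterior marginals of the parameters then
#'   equal their priors, which is used as a sampler validation.
#' @param max_restarts re-initialisation attempts if the initial density
#'   is not finite.
#' @return A `posterior_samples` object: list with `draws` (array kept x
#'   parameter x chain, natural scale), `log_density` (kept x chain),
#'   `config`, `priors`, and `centre0`.
#' @export
run_mcmc <- function(counts, receivers, covariates,
                     priors = default_priors(), config = mcmc_config(),
                     emissions_per_step = 6L, dt = 720,
                     prior_only = FALSE, max_restarts = 10L) {
  n <- nrow(counts)
  if (!prior_only && nrow(receivers) < 2) stop_invalid("need >= 2 receivers")
  if (n < 50) stop_invalid("need >= 50 time steps")
  stopifnot(nrow(covariates) == n)
  centre0 <- detection_centroid(counts, receivers)
  cells <- cell_index(covariates$daylight, covariates$noise)

  # initial latent path: per-step detection-weighted centroids, snapped to
  # the previous position when they barely move (or no detections), giving
  # plausible hidden runs; states are hidden exactly on the snapped steps
  cmat <- unclass(counts)
  pos0 <- matrix(NA_real_, n, 2)
  states0 <- integer(n)
  prev <- centre0
  snap <- 40  # m; initialisation heuristic only
  for (i in seq_len(n)) {
    w <- cmat[i, ]
    moved <- FALSE
    if (sum(w) > 0) {
      cen <- c(sum(w * receivers$x), sum(w * receivers$y)) / sum(w)
      if (i == 1 || sqrt(sum((cen - prev)^2)) > snap) {
        prev <- cen
        moved <- TRUE
      }
    }
    pos0[i, ] <- prev
    states0[i] <- if (i == 1 || moved) STATE_SWIMMING else STATE_HIDDEN
  }

  init_params <- c(
    cx = centre0[1], cy = centre0[2],
    lk = log(stats::qgamma(0.5, shape = priors$k_shape) * priors$k_scale),
    radius = (priors$radius_min + priors$radius_max) / 2,
    d50 = (priors$d50_min + priors$d50_max) / 2,
    ls = priors$log_neg_slope_mean,
    eta = rep(priors$logit_pq_mean, 8))

  pv <- priors_vector(priors, centre0)
  n_iter <- config$burn_in + config$n_keep * config$thin
  draws <- array(NA_real_,
                 dim = c(config$n_keep, length(PARAM_NAMES), config$n_chains),
                 dimnames = list(NULL, PARAM_NAMES, NULL))
  ld <- matrix(NA_real_, config$n_keep, config$n_chains)

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * chain)
    init <- init_params
    res <- NULL
    for (attempt in 0:max_restarts) {
      if (attempt > 0) {  # jitter the starting point
        init["radius"] <- runif(1, priors$radius_min, priors$radius_max)
        init["d50"] <- runif(1, priors$d50_min, priors$d50_max)
        init["lk"] <- init_params["lk"] + rnorm(1, 0, 1)
      }
      res <- ssm_mcmc_chain(cmat, receivers$x, receivers$y,
                            as.integer(cells), as.integer(emissions_per_step),
                            dt, pv, as.numeric(init), pos0,
                            as.integer(states0),
                            as.integer(n_iter), as.integer(config$burn_in),
                            as.integer(config$thin), isTRUE(prior_only))
      if (isTRUE(res$ok)) break
    }
    if (!isTRUE(res$ok)) {
      stop_invalid("initial log density not finite after ", max_restarts,
                   " restarts")
    }
    draws[, , chain] <- res$draws
    ld[, chain] <- res$log_density
  }
  structure(list(draws = draws, log_density = ld, config = config,
                 priors = priors, centre0 = centre0,
                 parameters = PARAM_NAMES),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_samples: %d chains x %d kept draws x %d parameters\n",
              d[3], d[1], d[2]))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' The classic potential scale reduction factor per parameter:
#' `R = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B/n` the variance of the chain means.  Values below 1.1
#' are conventionally taken to indicate convergence.  With zero
#' between-chain variance the statistic is <= 1 by construction.
#'
#' @param samples a `posterior_samples` object, or a kept x parameter x
#'   chain array.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  stopifnot(length(dim(draws)) == 3)
  n <- dim(draws)[1]
  m <- dim(draws)[3]
  if (m < 2) stop_invalid("need >= 2 chains for the Gelman-Rubin statistic")
  if (n < 10) stop_invalid("need >= 10 draws per chain")
  out <- apply(draws, 2, function(x) {  # x: n x m
    W <- mean(apply(x, 2, var))
    B_over_n <- var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
  setNames(out, dimnames(draws)[[2]])
}

#' Posterior summary: means, credibility intervals, R-hat
#'
#' Pools the chains and reports, per parameter, the posterior mean and
#' the equal-tailed Bayesian credibility interval at `level` (default
#' 95%), plus the Gelman-Rubin statistic when at least two chains are
#' available.
#'
#' @param samples a `posterior_samples` object.
#' @param level credibility level, default 0.95.
#' @return A `posterior_summary` data frame with columns `parameter`,
#'   `mean`, `lower`, `upper`, `rhat`.
#' @export
summarize_posterior <- function(samples, level = 0.95) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  stopifnot(length(dim(draws)) == 3, dim(draws)[1] >= 1)
  a <- (1 - level) / 2
  params <- dimnames(draws)[[2]]
  pooled <- apply(draws, 2, function(x) {
    v <- as.vector(x)
    c(mean(v), quantile(v, c(a, 1 - a), names = FALSE, type = 7))
  })
  rhat <- if (dim(draws)[3] >= 2) gelman_rubin(draws) else rep(NA_real_, length(params))
  out <- data.frame(parameter = params, mean = pooled[1, ],
                    lower = pooled[2, ], upper = pooled[3, ],
                    rhat = unname(rhat), row.names = NULL)
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Home-range area from the radius
#'
#' Area of the circular home range, `pi * radius^2`, converted to square
#' kilometres.
#'
#' @param radius home-range radius in metres (>= 0).
#' @return Area in km^2.
#' @examples
#' home_range_area(84.25)  # ~0.02 km^2
#' @export
home_range_area <- function(radius) {
  check_finite(radius, "radius")
  if (any(radius < 0)) stop_invalid("radius must be >= 0")
  pi * radius^2 * 1e-6
}
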
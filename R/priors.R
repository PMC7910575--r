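#' Prior distributions for the state-space model
#'
#' Defaults follow the home-range SSM literature for this receiver
#' technology: switching probabilities have a truncated-normal prior at
#' the logit scale (mean 0, sd 10, truncated to (-20, 20), virtually flat
#' on (0, 1)); the detection inflection point `d50` is uniform on
#' (-1000, 200) m; the home-range `radius` is uniform on (50, 1000) m; the
#' attraction strength `k` is gamma(shape 0.1, scale 0.1); the home-range
#' centre is uniform on a disc of radius 1000 m around the
#' detection-weighted receiver centroid.  The logistic detection slope has
#' no stated prior in that literature; a weakly-informative normal on
#' `log(-slope)` centred at log(0.02 per metre) (sd 1) is used, matching
#' a ~300-m detection range.
#'
#' @param logit_pq_mean,logit_pq_sd,logit_pq_lo,logit_pq_hi truncated
#'   normal on logit(p) and logit(q).
#' @param d50_min,d50_max uniform bounds for the inflection point (m).
#' @param log_neg_slope_mean,log_neg_slope_sd normal prior on
#'   `log(-slope)`.
#' @param radius_min,radius_max uniform bounds for the radius (m).
#' @param k_shape,k_scale gamma prior for `k` (per second).
#' @param centre_radius radius (m) of the uniform disc prior for the
#'   home-range centre around the detection-weighted receiver centroid.
#' @return An object of class `ssm_priors`.
#' @export
default_priors <- function(logit_pq_mean = 0, logit_pq_sd = 10,
                           logit_pq_lo = -20, logit_pq_hi = 20,
                           d50_min = -1000, d50_max = 200,
                           log_neg_slope_mean = log(0.02),
                           log_neg_slope_sd = 1,
                           radius_min = 50, radius_max = 1000,
                           k_shape = 0.1, k_scale = 0.1,
                           centre_radius = 1000) {
  structure(list(logit_pq_mean = logit_pq_mean, logit_pq_sd = logit_pq_sd,
                 logit_pq_lo = logit_pq_lo, logit_pq_hi = logit_pq_hi,
                 d50_min = d50_min, d50_max = d50_max,
                 log_neg_slope_mean = log_neg_slope_mean,
                 log_neg_slope_sd = log_neg_slope_sd,
                 radius_min = radius_min, radius_max = radius_max,
                 k_shape = k_shape, k_scale = k_scale,
                 centre_radius = centre_radius),
            class = "ssm_priors")
}

# log prior density over the sampler's coordinates:
# (cx, cy, log k, radius, d50, log(-slope), eta[1..8] = logit p/q).
# Returns -Inf outside the support (including the k*dt < 1 stability
# region).
log_prior <- function(cx, cy, lk, radius, d50, ls, eta, priors, centre0, dt) {
  p <- priors
  if (radius < p$radius_min || radius > p$radius_max) return(-Inf)
  if (d50 < p$d50_min || d50 > p$d50_max) return(-Inf)
  if (any(eta < p$logit_pq_lo | eta > p$logit_pq_hi)) return(-Inf)
  k <- exp(lk)
  if (!is.finite(k) || k * dt >= 1) return(-Inf)
  if ((cx - centre0[1])^2 + (cy - centre0[2])^2 > p$centre_radius^2) {
    return(-Inf)
  }
  lp <- -log(pi * p$centre_radius^2)                      # centre disc
  lp <- lp - log(p$radius_max - p$radius_min)             # radius
  lp <- lp - log(p$d50_max - p$d50_min)                   # d50
  lp <- lp + dgamma(k, shape = p$k_shape, scale = p$k_scale, log = TRUE) + lk
  lp <- lp + dnorm(ls, p$log_neg_slope_mean, p$log_neg_slope_sd, log = TRUE)
  z <- stats::pnorm(p$logit_pq_hi, p$logit_pq_mean, p$logit_pq_sd) -
    stats::pnorm(p$logit_pq_lo, p$logit_pq_mean, p$logit_pq_sd)
  lp + sum(dnorm(eta, p$logit_pq_mean, p$logit_pq_sd, log = TRUE) - log(z))
}

# flatten priors for the C++ sampler
priors_vector <- function(priors, centre0) {
  c(centre0x = centre0[1], centre0y = centre0[2],
    centre_radius = priors$centre_radius,
    k_shape = priors$k_shape, k_scale = priors$k_scale,
    radius_min = priors$radius_min, radius_max = priors$radius_max,
    d50_min = priors$d50_min, d50_max = priors$d50_max,
    ls_mean = priors$log_neg_slope_mean, ls_sd = priors$log_neg_slope_sd,
    eta_mean = priors$logit_pq_mean, eta_sd = priors$logit_pq_sd,
    eta_lo = priors$logit_pq_lo, eta_hi = priors$logit_pq_hi)
}

#' MCMC configuration
#'
#' Defaults are the reference chain settings: 3 independent chains, the
#' first 1000 iterations discarded as burn-in, one of every 10 iterations
#' kept, 10,000 kept draws per chain.
#'
#' @param n_chains number of independent chains.
#' @param n_keep kept (post-thinning) draws per chain.
#' @param burn_in iterations discarded at the start of each chain.
#' @param thin keep one of every `thin` post-burn-in iterations.
#' @param seed integer seed; chain c uses `seed + c` offsets internally.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_keep = 10000L, burn_in = 1000L,
                        thin = 10L, seed = 1L) {
  stopifnot(n_chains >= 1, n_keep >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_keep = as.integer(n_keep),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}
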
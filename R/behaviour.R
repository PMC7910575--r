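#' Two-state behavioural transition matrix
#'
#' Builds the 2x2 row-stochastic matrix governing switching between
#' swimming (state 1) and hidden (state 2):
#' \deqn{T = \begin{pmatrix} p & 1-p \\ 1-q & q \end{pmatrix}}
#' where `p` is the probability of remaining swimming and `q` the
#' probability of remaining hidden between consecutive time steps.
#'
#' @param p probability of staying in the swimming state.
#' @param q probability of staying in the hidden state.
#' @return A 2x2 numeric matrix of class `transition_matrix` with dimnames
#'   `c("swimming", "hidden")`.
#' @examples
#' transition_matrix(0.8, 0.6)
#' @export
transition_matrix <- function(p, q) {
  check_prob(p, "p")
  check_prob(q, "q")
  m <- matrix(c(p, 1 - q, 1 - p, q), nrow = 2,
              dimnames = list(c("swimming", "hidden"),
                              c("swimming", "hidden")))
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Covariate-indexed set of transition matrices
#'
#' The switching probabilities depend on two binary covariates, daylight
#' and the presence of motorboat-noise peaks, crossed into four transition
#' matrices (day/noise, day/silence, night/noise, night/silence), for a
#' total of 8 free probabilities per individual.
#'
#' @param day_noise,day_silence,night_noise,night_silence
#'   [transition_matrix()] objects for the four covariate combinations.
#' @return An object of class `transition_params`: a named list of the four
#'   matrices.
#' @examples
#' tp <- transition_params(
#'   day_noise     = transition_matrix(0.9, 0.7),
#'   day_silence   = transition_matrix(0.9, 0.6),
#'   night_noise   = transition_matrix(0.4, 0.9),
#'   night_silence = transition_matrix(0.4, 0.9))
#' select_matrix(tp, daylight = 1, noise = 0)
#' @export
transition_params <- function(day_noise, day_silence, night_noise,
                              night_silence) {
  mats <- list(day_noise = day_noise, day_silence = day_silence,
               night_noise = night_noise, night_silence = night_silence)
  ok <- vapply(mats, inherits, logical(1), what = "transition_matrix")
  if (!all(ok)) stop_invalid("all four entries must be transition_matrix objects")
  structure(mats, class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat("Transition probabilities (p = stay swimming, q = stay hidden):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s p = %.3f  q = %.3f\n", nm, x[[nm]][1, 1], x[[nm]][2, 2]))
  }
  invisible(x)
}

# cell name for a (daylight, noise) pair of 0/1 flags
covariate_cell <- function(daylight, noise) {
  paste0(ifelse(daylight == 1, "day", "night"),
         ifelse(noise == 1, "_noise", "_silence"))
}

#' Select the transition matrix for a covariate combination
#'
#' @param params a [transition_params()] object.
#' @param daylight 1 for day, 0 for night.
#' @param noise 1 if a motorboat noise peak is present in the step, else 0.
#' @return The [transition_matrix()] keyed by the covariate pair.
#' @export
select_matrix <- function(params, daylight, noise) {
  if (!inherits(params, "transition_params")) {
    stop_invalid("params must be a transition_params object")
  }
  if (!daylight %in% c(0, 1) || !noise %in% c(0, 1)) {
    stop_invalid("daylight and noise must be 0 or 1")
  }
  cell <- covariate_cell(daylight, noise)
  m <- params[[cell]]
  if (is.null(m)) stop_invalid("missing transition matrix for cell ", cell)
  m
}

#' Logit-linear link for a continuous covariate
#'
#' The continuous extension of the covariate model: instead of crossing
#' binary covariates into separate matrices, a switching probability can be
#' modelled as `inverse-logit(beta1 + beta2 * v)` in a continuous covariate
#' `v` (e.g. noise level in dB), giving a sigmoidal response in (0, 1).
#' The default fitter uses the binary (matrix-selection) form; this link is
#' provided for the continuous variant.
#'
#' @param beta1 intercept at the logit scale.
#' @param beta2 slope at the logit scale.
#' @param v covariate value(s).
#' @return Probability (vectorised over `v`).
#' @examples
#' logit_link(2, 0, 7)  # 1 / (1 + exp(-2))
#' @export
logit_link <- function(beta1, beta2, v) {
  check_finite(c(beta1, beta2), "beta coefficients")
  check_finite(v, "v")
  plogis(beta1 + beta2 * v)
}

#' Covariate series for the switching model
#'
#' @param daylight binary vector (1 day, 0 night), one entry per step.
#' @param noise binary vector (1 noise peak present, 0 absent), same length.
#' @param times optional 0-based step indices (default `0:(n-1)`).
#' @return A `covariate_series` data frame with columns `step`, `daylight`,
#'   `noise`.
#' @export
covariate_series <- function(daylight, noise,
                             times = seq_along(daylight) - 1L) {
  if (length(daylight) != length(noise) || length(daylight) != length(times)) {
    stop_invalid("daylight, noise and times must have equal length")
  }
  if (!all(daylight %in% c(0, 1)) || !all(noise %in% c(0, 1))) {
    stop_invalid("covariates must be binary (0/1)")
  }
  structure(data.frame(step = as.integer(times),
                       daylight = as.integer(daylight),
                       noise = as.integer(noise)),
            class = c("covariate_series", "data.frame"))
}

#' @rdname covariate_series
#' @param path CSV path with header `step,daylight,noise`.
#' @export
read_covariates <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("step", "daylight", "noise") %in% names(d)))
  covariate_series(d$daylight, d$noise, d$step)
}

#' @rdname covariate_series
#' @param covariates a `covariate_series`.
#' @export
write_covariates <- function(covariates, path) {
  write.csv(as.data.frame(covariates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate the behavioural state chain
#'
#' Realises the two-state Markov chain under the covariate-indexed
#' transition matrices.  The matrix applied to the transition from step
#' n-1 to step n is selected by the covariates at step n.
#'
#' @param params a [transition_params()] object.
#' @param covariates a [covariate_series()]; its length sets the number of
#'   steps.
#' @param init initial state at the first step (1 swimming, 2 hidden).
#' @param seed integer seed.
#' @return Integer vector of states, one per covariate row.
#' @examples
#' tp <- transition_params(
#'   transition_matrix(0.9, 0.8), transition_matrix(0.9, 0.8),
#'   transition_matrix(0.3, 0.9), transition_matrix(0.3, 0.9))
#' cov <- covariate_series(rep(c(1, 0), each = 50), rep(0, 100))
#' s <- simulate_states(tp, cov, init = 1, seed = 42)
#' table(s)
#' @export
simulate_states <- function(params, covariates, init = STATE_SWIMMING,
                            seed = 1L) {
  if (nrow(covariates) == 0) stop_invalid("covariates must be non-empty")
  if (!init %in% c(STATE_SWIMMING, STATE_HIDDEN)) {
    stop_invalid("init must be 1 or 2")
  }
  n <- nrow(covariates)
  states <- integer(n)
  states[1] <- as.integer(init)
  set.seed(seed)
  u <- runif(n)
  for (i in seq_len(n)[-1]) {
    m <- select_matrix(params, covariates$daylight[i], covariates$noise[i])
    stay <- m[states[i - 1], states[i - 1]]
    states[i] <- if (u[i] <= stay) states[i - 1] else 3L - states[i - 1]
  }
  states
}
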
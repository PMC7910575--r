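# Independent brute-force oracles used to validate the likelihood code.
# These deliberately re-derive every term with plain stats functions and
# exhaustive enumeration instead of calling the package's own likelihood
# implementations.

CHI2_2 <- qchisq(0.95, df = 2)

# movement density of one swimming step, per axis
oracle_step_dens <- function(to, from, centre, k, radius, dt, log = TRUE) {
  sv <- k * dt * (2 - k * dt) * radius^2 / CHI2_2
  mu <- from + k * dt * (centre - from)
  sum(dnorm(to, mu, sqrt(sv), log = TRUE))
}

# state-sequence density of a fixed position path, summed over all 2^N
# state sequences by enumeration (hidden = exact equality indicator,
# swimming = movement density; step 1 contributes the initial weights)
oracle_forward <- function(positions, p, q, daylight, noise, centre, k,
                           radius, dt, init_dist = c(0.5, 0.5)) {
  n <- nrow(positions)
  cellname <- function(i) {
    paste0(ifelse(daylight[i] == 1, "day", "night"),
           ifelse(noise[i] == 1, "_noise", "_silence"))
  }
  grid <- as.matrix(expand.grid(rep(list(1:2), n)))
  lps <- apply(grid, 1, function(s) {
    lp <- log(init_dist[s[1]])
    for (i in seq_len(n)[-1]) {
      cl <- cellname(i)
      pp <- p[[cl]]; qq <- q[[cl]]
      tm <- matrix(c(pp, 1 - qq, 1 - pp, qq), 2)
      lp <- lp + log(tm[s[i - 1], s[i]])
      if (s[i] == 2) {
        if (!all(positions[i, ] == positions[i - 1, ])) lp <- -Inf
      } else {
        lp <- lp + oracle_step_dens(positions[i, ], positions[i - 1, ],
                                    centre, k, radius, dt)
      }
      if (!is.finite(lp)) break
    }
    lp
  })
  mx <- max(lps)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(lps - mx)))
}

# full joint log density (priors + chain + movement + detection) for a
# completely specified configuration, written out longhand
oracle_joint <- function(track, par, counts, cov, rec, centre0,
                         m = 6L, dt = 720) {
  # priors (same coordinates as the sampler: log k, log(-slope), logits)
  lp <- 0
  if (par$radius < 50 || par$radius > 1000) return(-Inf)
  if (par$d50 < -1000 || par$d50 > 200) return(-Inf)
  if (par$k * dt >= 1) return(-Inf)
  if (sum((c(par$hr_x, par$hr_y) - centre0)^2) > 1000^2) return(-Inf)
  lp <- lp - log(pi * 1000^2) - log(950) - log(1200)
  lp <- lp + dgamma(par$k, shape = 0.1, scale = 0.1, log = TRUE) + log(par$k)
  lp <- lp + dnorm(log(-par$slope), log(0.02), 1, log = TRUE)
  z <- pnorm(20, 0, 10) - pnorm(-20, 0, 10)
  etas <- qlogis(unlist(par$pq))
  if (any(abs(etas) > 20)) return(-Inf)
  lp <- lp + sum(dnorm(etas, 0, 10, log = TRUE) - log(z))

  # initial state + position
  v1 <- par$radius^2 / CHI2_2
  ll <- log(0.5) + dnorm(track$x[1], par$hr_x, sqrt(v1), log = TRUE) +
    dnorm(track$y[1], par$hr_y, sqrt(v1), log = TRUE)
  n <- nrow(track)
  for (i in seq_len(n)[-1]) {
    cl <- paste0(ifelse(cov$daylight[i] == 1, "day", "night"),
                 ifelse(cov$noise[i] == 1, "_noise", "_silence"))
    pq <- par$pq[[cl]]
    tm <- matrix(c(pq[1], 1 - pq[2], 1 - pq[1], pq[2]), 2)
    ll <- ll + log(tm[track$state[i - 1], track$state[i]])
    if (track$state[i] == 2) {
      if (track$x[i] != track$x[i - 1] || track$y[i] != track$y[i - 1]) {
        return(-Inf)
      }
    } else {
      ll <- ll + oracle_step_dens(c(track$x[i], track$y[i]),
                                  c(track$x[i - 1], track$y[i - 1]),
                                  c(par$hr_x, par$hr_y), par$k, par$radius, dt)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(rec))) {
      d <- sqrt((track$x[i] - rec$x[j])^2 + (track$y[i] - rec$y[j])^2)
      pd <- plogis(par$slope * (d - par$d50))
      ll <- ll + dbinom(counts[i, j], m, pd, log = TRUE)
    }
  }
  unname(lp + ll)
}

# small instance shared by the likelihood tests
tiny_instance <- function(n = 3, seed = 11) {
  set.seed(seed)
  rec <- receiver_array(c("a", "b"), c(-75, 75), c(0, 0))
  states <- c(1L, 1L, rep(c(2L, 1L), length.out = n - 2))
  x <- numeric(n); y <- numeric(n)
  x[1] <- 10; y[1] <- -5
  for (i in seq_len(n)[-1]) {
    if (states[i] == 2) {
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
    } else {
      x[i] <- x[i - 1] + rnorm(1, 0, 30)
      y[i] <- y[i - 1] + rnorm(1, 0, 30)
    }
  }
  track <- data.frame(step = 0:(n - 1), x = x, y = y, state = states)
  class(track) <- c("fish_track", "data.frame")
  cov <- covariate_series(rep(c(1L, 0L), length.out = n),
                          rep(c(0L, 1L), length.out = n))
  counts <- matrix(rbinom(2 * n, 6, 0.5), nrow = n)
  colnames(counts) <- rec$receiver_id
  pq <- list(day_noise = c(0.8, 0.6), day_silence = c(0.7, 0.5),
             night_noise = c(0.4, 0.9), night_silence = c(0.3, 0.85))
  par <- list(hr_x = 15, hr_y = -10, k = 6e-4, radius = 120, d50 = 140,
              slope = -0.018, pq = pq)
  list(track = track, cov = cov, counts = counts, rec = rec, par = par,
       centre0 = c(0, 0))
}

# package-facing parameter list for joint_log_density()
as_pkg_params <- function(par) {
  tp <- transition_params(
    day_noise = transition_matrix(par$pq$day_noise[1], par$pq$day_noise[2]),
    day_silence = transition_matrix(par$pq$day_silence[1], par$pq$day_silence[2]),
    night_noise = transition_matrix(par$pq$night_noise[1], par$pq$night_noise[2]),
    night_silence = transition_matrix(par$pq$night_silence[1],
                                      par$pq$night_silence[2]))
  list(hr_x = par$hr_x, hr_y = par$hr_y, k = par$k, radius = par$radius,
       d50 = par$d50, slope = par$slope, transition = tp)
}
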
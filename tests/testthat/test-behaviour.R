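test_that("transition matrices have the (p, 1-p; 1-q, q) layout and are stochastic", {
  m <- transition_matrix(0.8, 0.6)
  expect_equal(unclass(m)[1, ], c(swimming = 0.8, hidden = 0.2))
  expect_equal(unclass(m)[2, ], c(swimming = 0.4, hidden = 0.6))
  expect_equal(unname(transition_matrix(1, 1)[1:2, 1:2]), diag(2))
  expect_equal(unname(transition_matrix(0, 0)[1:2, 1:2]),
               matrix(c(0, 1, 1, 0), 2))
  for (p in seq(0, 1, by = 0.25)) {
    for (q in c(0, 0.37, 1)) {
      expect_lte(max(abs(rowSums(transition_matrix(p, q)) - 1)), 1e-12)
    }
  }
  expect_error(transition_matrix(1.2, 0.5), "\\[0, 1\\]")
  expect_error(transition_matrix(0.5, -0.1), "\\[0, 1\\]")
})

test_that("covariates select the matching matrix out of the four-cell cross", {
  mats <- list(day_noise = transition_matrix(0.1, 0.9),
               day_silence = transition_matrix(0.2, 0.8),
               night_noise = transition_matrix(0.3, 0.7),
               night_silence = transition_matrix(0.4, 0.6))
  tp <- do.call(transition_params, mats)
  expect_identical(select_matrix(tp, daylight = 1, noise = 1), mats$day_noise)
  expect_identical(select_matrix(tp, daylight = 0, noise = 0),
                   mats$night_silence)
  expect_identical(select_matrix(tp, daylight = 0, noise = 1),
                   mats$night_noise)
  expect_error(select_matrix(tp, 2, 0), "0 or 1")

  same <- transition_params(mats$day_noise, mats$day_noise, mats$day_noise,
                            mats$day_noise)
  expect_identical(select_matrix(same, 1, 0), select_matrix(same, 0, 1))
})

test_that("the logit link is the inverse-logit of a linear predictor", {
  expect_equal(logit_link(0, 0, 123), 0.5)
  expect_equal(logit_link(2, 0, 7), 1 / (1 + exp(-2)), tolerance = 1e-12)
  v <- seq(-5, 5, by = 0.5)
  out <- logit_link(1, -0.8, v)
  expect_true(all(diff(out) < 0))      # beta2 < 0 => decreasing
  expect_true(all(out > 0 & out < 1))
  # round trip through the logit on a probability grid
  probs <- seq(0.001, 0.999, length.out = 101)
  expect_equal(logit_link(qlogis(probs), 0, 0), probs, tolerance = 1e-10)
  expect_error(logit_link(Inf, 0, 1), "finite")
})

test_that("state chains hit the stationary occupancy of their (p, q) pair", {
  n <- 1e5
  cov <- covariate_series(rep(c(1L, 0L), n / 2), rep(0L, n))
  shy_m <- transition_matrix(0.2, 0.95)
  shy <- transition_params(shy_m, shy_m, shy_m, shy_m)
  s <- simulate_states(shy, cov, init = 2L, seed = 5)
  # stationary fraction hidden: (1-p) / ((1-p) + (1-q))
  expect_equal(mean(s == 2L), 0.8 / 0.85, tolerance = 0.02 / 0.94)

  bold_m <- transition_matrix(0.95, 0.2)
  bold <- transition_params(bold_m, bold_m, bold_m, bold_m)
  s2 <- simulate_states(bold, cov, init = 1L, seed = 5)
  expect_equal(mean(s2 == 1L), 0.8 / 0.85, tolerance = 0.02 / 0.94)

  absorbing <- transition_params(transition_matrix(1, 1), transition_matrix(1, 1),
                                 transition_matrix(1, 1), transition_matrix(1, 1))
  expect_true(all(simulate_states(absorbing, cov, init = 1L, seed = 1) == 1L))
})

test_that("empirical transition frequencies recover p and q", {
  n <- 4e4
  cov <- covariate_series(rep(1L, n), rep(0L, n))
  m <- transition_matrix(0.7, 0.4)
  tp <- transition_params(m, m, m, m)
  s <- simulate_states(tp, cov, init = 1L, seed = 21)
  from <- s[-n]; to <- s[-1]
  p_hat <- mean(to[from == 1L] == 1L)
  q_hat <- mean(to[from == 2L] == 2L)
  expect_equal(p_hat, 0.7, tolerance = 0.03)
  expect_equal(q_hat, 0.4, tolerance = 0.05)
  expect_identical(s, simulate_states(tp, cov, init = 1L, seed = 21))
})

test_that("covariate series validate and round-trip as CSV", {
  cov <- covariate_series(c(1, 0, 1), c(0, 0, 1))
  path <- file.path(tempdir(), "cov.csv")
  write_covariates(cov, path)
  expect_equal(as.data.frame(read_covariates(path)), as.data.frame(cov))
  expect_error(covariate_series(c(1, 2), c(0, 0)), "binary")
  expect_error(covariate_series(c(1, 0), c(0, 0, 1)), "equal length")
})
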
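test_that("the joint log density matches an independent longhand oracle", {
  inst <- tiny_instance(n = 3)
  got <- joint_log_density(inst$track, as_pkg_params(inst$par),
                           detection_series(inst$counts,
                                            emissions_per_step = 6L),
                           inst$cov, inst$rec, centre0 = inst$centre0)
  want <- oracle_joint(inst$track, inst$par, inst$counts, inst$cov,
                       inst$rec, inst$centre0)
  expect_equal(got, want, tolerance = 1e-10)

  # and the compiled sampler target agrees with the R reference
  pv <- swimhide:::priors_vector(default_priors(), inst$centre0)
  cells <- swimhide:::cell_index(inst$cov$daylight, inst$cov$noise)
  params_vec <- c(inst$par$hr_x, inst$par$hr_y, log(inst$par$k),
                  inst$par$radius, inst$par$d50, log(-inst$par$slope),
                  qlogis(unlist(inst$par$pq)))
  got_cpp <- swimhide:::ssm_joint_loglik_cpp(
    inst$counts, inst$rec$x, inst$rec$y, as.integer(cells), 6L, 720, pv,
    params_vec, cbind(inst$track$x, inst$track$y),
    as.integer(inst$track$state), FALSE)
  expect_equal(got_cpp, want, tolerance = 1e-10)
})

test_that("support violations give -Inf, never an error", {
  inst <- tiny_instance(n = 3)
  par_bad <- as_pkg_params(inst$par)
  par_bad$radius <- 2000  # outside U(50, 1000)
  counts <- detection_series(inst$counts, emissions_per_step = 6L)
  expect_identical(joint_log_density(inst$track, par_bad, counts, inst$cov,
                                     inst$rec, centre0 = inst$centre0), -Inf)

  broken <- inst$track
  broken$x[2] <- broken$x[2] + 1  # hidden step that moved
  broken$state[2] <- 2L
  expect_identical(joint_log_density(broken, as_pkg_params(inst$par), counts,
                                     inst$cov, inst$rec,
                                     centre0 = inst$centre0), -Inf)
})

test_that("a certain detection contributes zero log likelihood", {
  # binomial(6, p = 1) observed at 6: the observation term vanishes
  par <- detection_params(d50 = 1e9, slope = -0.02)
  pd <- detection_probability(0, par)
  expect_identical(dbinom(6L, 6L, pd, log = TRUE), 0)
})

test_that("the forward algorithm equals exhaustive state enumeration", {
  mv <- movement_params(15, -10, k = 6e-4, radius = 120)
  pq <- list(day_noise = c(0.8, 0.6), day_silence = c(0.7, 0.5),
             night_noise = c(0.4, 0.9), night_silence = c(0.3, 0.85))
  tp <- transition_params(
    day_noise = transition_matrix(0.8, 0.6),
    day_silence = transition_matrix(0.7, 0.5),
    night_noise = transition_matrix(0.4, 0.9),
    night_silence = transition_matrix(0.3, 0.85))
  p_list <- lapply(pq, `[`, 1)
  q_list <- lapply(pq, `[`, 2)

  for (n in c(1, 2, 5, 10)) {
    set.seed(100 + n)
    pos <- matrix(cumsum(rnorm(2 * n, 0, 20)), ncol = 2)
    # plant exact repeats so hidden states are reachable
    if (n >= 3) pos[3, ] <- pos[2, ]
    if (n >= 7) pos[7, ] <- pos[6, ]
    cov <- covariate_series(rep(c(1L, 0L), length.out = n),
                            rep(c(0L, 1L), length.out = n))
    got <- forward_state_loglik(pos, tp, cov, mv)
    want <- oracle_forward(pos, p_list, q_list, cov$daylight, cov$noise,
                           c(mv$hr_x, mv$hr_y), mv$k, mv$radius, mv$dt)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("a degenerate all-swimming chain reduces to the pure BRW density", {
  mv <- movement_params(0, 0, k = 5e-4, radius = 100)
  stay <- transition_matrix(1, 0.5)
  tp <- transition_params(stay, stay, stay, stay)
  n <- 6
  set.seed(3)
  pos <- matrix(cumsum(rnorm(2 * n, 0, 25)), ncol = 2)
  cov <- covariate_series(rep(1L, n), rep(0L, n))
  got <- forward_state_loglik(pos, tp, cov, mv, init_dist = c(1, 0))
  kdt <- mv$k * mv$dt
  sv <- kdt * (2 - kdt) * mv$radius^2 / qchisq(0.95, 2)
  want <- 0
  for (i in 2:n) {
    mu <- pos[i - 1, ] + mv$k * mv$dt * (c(0, 0) - pos[i - 1, ])
    want <- want + sum(dnorm(pos[i, ], mu, sqrt(sv), log = TRUE))
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the Gelman-Rubin statistic flags separated chains and passes mixed ones", {
  set.seed(6)
  n <- 1e4
  apart <- array(c(rnorm(n, 0, 1), rnorm(n, 100, 1)), dim = c(n, 1, 2),
                 dimnames = list(NULL, "x", NULL))
  expect_gt(gelman_rubin(apart)["x"], 10)

  same <- array(rnorm(3 * n), dim = c(n, 1, 3),
                dimnames = list(NULL, "x", NULL))
  expect_equal(unname(gelman_rubin(same)["x"]), 1, tolerance = 0.01)

  frozen <- array(rep(rnorm(n), 2), dim = c(n, 1, 2),
                  dimnames = list(NULL, "x", NULL))
  expect_lte(gelman_rubin(frozen)["x"], 1)  # zero between-chain variance

  expect_error(gelman_rubin(array(rnorm(20), c(10, 2, 1))), "2 chains")

  # independent cross-check against coda on irregular chains
  set.seed(9)
  draws <- array(rnorm(3 * 2000, mean = rep(c(0, 0.2, -0.1), each = 2000)),
                 dim = c(2000, 1, 3), dimnames = list(NULL, "x", NULL))
  ours <- unname(gelman_rubin(draws)["x"])
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(1:3, function(ch) {
    coda::mcmc(draws[, 1, ch])
  })), autoburnin = FALSE, transform = FALSE)
  # coda applies a d.f. correction; agreement to ~1% is expected
  expect_equal(ours, unname(cd$psrf[1, 1]), tolerance = 0.01)
})

test_that("posterior summaries give pooled means and equal-tailed intervals", {
  const <- array(5, dim = c(100, 1, 3), dimnames = list(NULL, "c", NULL))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 5)
  expect_equal(s$upper - s$lower, 0)

  set.seed(8)
  norm <- array(rnorm(3 * 20000), dim = c(20000, 1, 3),
                dimnames = list(NULL, "z", NULL))
  s2 <- summarize_posterior(norm, level = 0.95)
  expect_equal(s2$lower, -1.96, tolerance = 0.03)
  expect_equal(s2$upper, 1.96, tolerance = 0.03)
  expect_true(s2$lower <= s2$mean && s2$mean <= s2$upper)
})

test_that("home-range area converts radius to square kilometres", {
  expect_equal(round(home_range_area(84.25), 2), 0.02)
  expect_identical(home_range_area(0), 0)
  expect_equal(home_range_area(564.19), 1.00, tolerance = 1e-4)
  expect_error(home_range_area(-5), ">= 0")
})
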
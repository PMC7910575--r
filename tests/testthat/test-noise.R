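test_that("calibration maps counts to micropascal and obeys dB arithmetic", {
  expect_true(all(calibrate(rep(0L, 100), -170, 0, 1)$pressure == 0))

  set.seed(1)
  raw <- sample(-1000:1000, 500, replace = TRUE)
  a <- calibrate(raw, -170, 0, 1)
  b <- calibrate(raw, -170, 6.0206, 1)  # +6.02 dB gain halves pressure
  expect_equal(b$pressure, a$pressure / 2, tolerance = 1e-4)

  # full-scale sinusoid: peak pressure = 10^(170/20) uPa
  n <- 44100
  sine <- round(32767 * sin(2 * pi * 1000 * (0:(n - 1)) / 44100))
  clip <- calibrate(sine, -170, 0, 1)
  expect_equal(max(clip$pressure), 10^(170 / 20) * 32767 / 32768,
               tolerance = 1e-6)
  expect_error(calibrate(raw, -170, 0), "calibration requires")
  expect_error(calibrate(c(40000L), -170, 0, 1), "16-bit")
})

test_that("SPL follows 10*log10(msp) with permutation and gain invariances", {
  expect_equal(compute_spl(rep(1, 441)), 0)
  x <- rnorm(441, 0, 10)
  expect_equal(compute_spl(x^0 * 10), 20)  # constant 10 uPa
  expect_equal(compute_spl(x), compute_spl(sample(x)))
  expect_equal(compute_spl(10 * x), compute_spl(x) + 20)

  # sampled sinusoid of amplitude A: SPL = 20*log10(A/sqrt(2))
  A <- 250
  t <- (0:44099) / 44100
  s <- A * sin(2 * pi * 441 * t)  # whole cycles in the window
  expect_equal(compute_spl(s), 20 * log10(A / sqrt(2)), tolerance = 1e-6)

  silent <- compute_spl(rep(0, 100), floor_db = -120)
  expect_equal(as.numeric(silent), -120)
  expect_true(isTRUE(attr(silent, "silent")))
})

test_that("per-second PSD peaks at the tone frequency and satisfies Parseval", {
  rate <- 44100
  t <- (0:(3 * rate - 1)) / rate
  tone <- audio_clip(100 * sin(2 * pi * 1000 * t), rate = rate)
  psd <- compute_psd(tone)
  expect_equal(ncol(psd$psd_db), 3)  # one spectrum per full second
  for (seg in 1:3) {
    expect_equal(psd$freq[which.max(psd$psd_db[, seg])], 1000)
  }

  set.seed(4)
  noise <- audio_clip(rnorm(2 * rate, 0, 50), rate = rate)
  p2 <- compute_psd(noise)
  segs <- matrix(noise$pressure, nrow = rate)
  df <- rate / rate  # 1 Hz bins on 1-s segments
  for (seg in 1:2) {
    integral <- sum(p2$psd_linear[, seg]) * df
    msp <- mean(segs[, seg]^2)
    expect_equal(integral, msp, tolerance = 1e-3)
  }
  expect_error(compute_psd(audio_clip(rnorm(100), rate = rate)), "shorter")
})

test_that("basal estimation is robust to loud outliers and reordering", {
  expect_equal(estimate_basal(rep(110, 100)), 110)
  spl <- c(rep(110, 90), rep(135, 10))  # 10% boat-like outliers
  expect_lt(abs(estimate_basal(spl) - 110), 0.5)
  expect_equal(estimate_basal(sample(spl)), estimate_basal(spl))
  expect_error(estimate_basal(rep(110, 10)), "at least")
})

test_that("noise peaks trigger at 1.8x basal mean squared pressure inclusively", {
  basal <- 110
  msp_ratio_to_db <- function(r) basal + 10 * log10(r)
  spl <- msp_ratio_to_db(c(1.9, 1.7, 1.8, 1.0))
  flags <- detect_noise_peaks(spl, basal, factor = 1.8)
  expect_identical(flags, c(1L, 0L, 1L, 0L))  # >= at the exact threshold

  # raising the factor can only remove flags
  for (f in c(2, 2.5, 4)) {
    expect_true(all(detect_noise_peaks(spl, basal, factor = f) <= flags))
  }
  # dB-scale variant compares factor * basal directly
  expect_identical(detect_noise_peaks(c(200, 190), basal, factor = 1.8,
                                      scale = "db"), c(1L, 0L))
})

test_that("step alignment ORs the per-second flags inside each step", {
  flags <- rep(0L, 3000)
  flags[c(100, 800, 801)] <- 1L
  out <- align_noise_to_steps(flags, seq_along(flags) - 1, origin = 0,
                              step_duration = 720)
  expect_identical(out$noise_flag, c(1L, 1L, 0L, 0L, 0L))
  none <- align_noise_to_steps(rep(0L, 1440), 0:1439, 0, 720)
  expect_true(all(none$noise_flag == 0L))
  expect_error(align_noise_to_steps(1L, -5, 0, 720), "before")
})

test_that("PCM WAV files round-trip bit-exactly", {
  set.seed(2)
  samples <- as.integer(sample(-32768:32767, 5000, replace = TRUE))
  path <- file.path(tempdir(), "roundtrip.wav")
  write_wav(samples, path, rate = 44100)
  back <- read_wav(path)
  expect_identical(back$samples, samples)
  expect_identical(back$rate, 44100L)
  expect_error(write_wav(40000, path), "clip")
})

test_that("injected boat bursts are recovered exactly; sub-threshold ones are not", {
  path <- file.path(tempdir(), "boat.wav")
  fx <- make_boat_wav(path, duration = 90, basal_spl = 120,
                      events = data.frame(start = c(20, 60),
                                          duration = c(3, 2),
                                          excess_db = c(6, 8)),
                      seed = 8)
  w <- read_wav(path)
  clip <- calibrate(w$samples, fx$calibration$sensitivity,
                    fx$calibration$gain, fx$calibration$full_scale_volts,
                    rate = w$rate)
  s <- spl_series(clip)
  basal <- estimate_basal(s)
  flags <- detect_noise_peaks(s, basal, factor = 1.8)
  truth <- fx$labels$flagged
  expect_identical(flags, truth)  # recall 1, false positives 0

  # an event below the 2.55 dB threshold margin stays unflagged
  fx2 <- make_boat_wav(file.path(tempdir(), "quietboat.wav"), duration = 70,
                       basal_spl = 120,
                       events = data.frame(start = 30, duration = 3,
                                           excess_db = 1),
                       seed = 9)
  w2 <- read_wav(fx2$path)
  clip2 <- calibrate(w2$samples, -170, 0, 1, rate = w2$rate)
  s2 <- spl_series(clip2)
  expect_true(all(detect_noise_peaks(s2, estimate_basal(s2), 1.8) == 0L))
})
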
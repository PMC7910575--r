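test_that("detection probability is logistic in distance with d50 at 0.5", {
  par <- detection_params(d50 = 150, slope = -0.02)
  expect_identical(detection_probability(150, par), 0.5)
  expect_equal(detection_probability(100, par), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  d <- seq(0, 2000, by = 10)
  pd <- detection_probability(d, par)
  expect_true(all(diff(pd) < 0))
  expect_true(all(pd > 0 & pd < 1))
  expect_lt(detection_probability(1e6, par), 1e-12)
  expect_error(detection_probability(-1, par), ">= 0")
  expect_error(detection_params(slope = 0.01), "negative")
})

test_that("simulated detections are binomial with the logistic mean", {
  rec <- make_receiver_grid(4, 150)
  p <- movement_params(0, 0, k = 5e-4, radius = 100)
  trk <- simulate_track(p, rep(2L, 200), start = c(0, 0), seed = 1)

  sure <- detection_params(d50 = 1e7, slope = -0.02)
  all6 <- simulate_detections(trk, rec, sure, seed = 1)
  expect_true(all(all6 == 6L))

  never <- detection_params(d50 = -1e7, slope = -0.5)
  expect_true(all(simulate_detections(trk, rec, never, seed = 1) == 0L))

  # fixed position: empirical mean within 2 binomial standard errors
  par <- detection_params(d50 = 150, slope = -0.02)
  n <- 1e4
  still <- simulate_track(p, rep(2L, n), start = c(40, 10), seed = 2)
  counts <- simulate_detections(still, rec, par, seed = 3)
  for (j in seq_len(nrow(rec))) {
    dist <- sqrt((40 - rec$x[j])^2 + (10 - rec$y[j])^2)
    pd <- detection_probability(dist, par)
    se <- sqrt(6 * pd * (1 - pd) / n)
    expect_lt(abs(mean(counts[, j]) - 6 * pd), 2.5 * se)
  }
  expect_true(all(counts >= 0 & counts <= 6))
  expect_identical(unclass(simulate_detections(still, rec, par, seed = 3)),
                   unclass(counts))
})

test_that("binning is half-open, conserves counts, and rejects early events", {
  origin <- as.POSIXct("2017-07-24 00:00:00", tz = "UTC")
  ev <- data.frame(timestamp = origin + c(0, 300, 800),
                   tag_id = "t1", receiver_id = "r1")
  b <- bin_detections(ev, step_duration = 720, origin = origin)
  expect_equal(as.vector(b), c(2L, 1L))

  empty <- bin_detections(ev[0, ], step_duration = 720, origin = origin,
                          n_steps = 4)
  expect_true(all(empty == 0L))
  expect_equal(nrow(empty), 4)

  set.seed(10)
  n_ev <- 10764L  # ten days of detections for the busiest fish
  big <- data.frame(timestamp = origin + runif(n_ev, 0, 10 * 86400),
                    tag_id = "t1",
                    receiver_id = sample(sprintf("r%02d", 1:14), n_ev, TRUE))
  binned <- bin_detections(big, 720, origin, n_steps = 1200)
  expect_identical(sum(binned), n_ev)

  expect_error(bin_detections(data.frame(timestamp = origin - 1,
                                         tag_id = "t", receiver_id = "r"),
                              720, origin), "before")
})

test_that("day/night classification is sunrise-inclusive and sunset-exclusive", {
  sun <- data.frame(date = as.Date("2017-07-24"),
                    sunrise = as.POSIXct("2017-07-24 04:30:00", tz = "UTC"),
                    sunset = as.POSIXct("2017-07-24 19:10:00", tz = "UTC"))
  ts <- as.POSIXct(c("2017-07-24 04:29:59", "2017-07-24 04:30:00",
                     "2017-07-24 12:00:00", "2017-07-24 19:09:59",
                     "2017-07-24 19:10:00", "2017-07-24 23:00:00"),
                   tz = "UTC")
  expect_identical(classify_day_night(ts, sun), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_error(classify_day_night(as.POSIXct("2017-07-25 10:00:00",
                                             tz = "UTC"), sun),
               "cover")
})

test_that("detection series validate bounds and round-trip as long CSV", {
  counts <- matrix(c(0L, 3L, 6L, 1L), 2, dimnames = list(NULL, c("a", "b")))
  ds <- detection_series(counts, emissions_per_step = 6L)
  path <- file.path(tempdir(), "det.csv")
  write_detections(ds, path)
  back <- read_detections(path, emissions_per_step = 6L)
  expect_equal(unclass(back)[, c("a", "b")], unclass(ds)[, c("a", "b")])
  expect_error(detection_series(matrix(7L, 1, 1), emissions_per_step = 6L),
               "exceed")
  expect_error(detection_series(matrix(-1L, 1, 1)), "non-negative")
})
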
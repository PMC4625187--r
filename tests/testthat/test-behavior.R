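test_that("pool geometry validates the platform position", {
  expect_error(pool_geometry(platform_center = c(0, 0.73)), "inside the pool")
  p <- pool_geometry()
  expect_equal(p$radius, 0.75)
  expect_equal(p$platform_radius, 0.045)
})

test_that("trajectory invariants are enforced", {
  p <- pool_geometry()
  expect_error(swim_trajectory(c(0, 1, 1), c(0, 0.1, 0.2), c(0, 0, 0), p),
               "strictly increasing")
  expect_error(swim_trajectory(c(0, 1), c(0, 0.9), c(0, 0), p),
               "exits the pool")
})

test_that("path length follows elementary geometry", {
  p <- pool_geometry()
  tr <- swim_trajectory(0:4, rep(0.1, 5), rep(0.2, 5), p)
  expect_equal(path_length(tr), 0)
  tr <- swim_trajectory(seq(0, 1, 0.1), seq(0, 0.6, length.out = 11),
                        rep(0, 11), p)
  expect_equal(path_length(tr), 0.6, tolerance = 1e-12)
  # quarter circle of radius 0.5 at 10 ms sampling
  th <- seq(0, pi / 2, length.out = 901)
  tr <- swim_trajectory(seq(0, 9, 0.01), 0.5 * cos(th), 0.5 * sin(th), p)
  expect_equal(path_length(tr), pi / 4, tolerance = 0.01 * pi / 4)
  expect_error(path_length(swim_trajectory(0, 0.1, 0.1, p)),
               "degenerate trajectory")
})

test_that("escape latency, timeout flag and velocity are consistent", {
  p <- pool_geometry()
  # straight approach at 0.25 m/s to the platform edge, 0.6 m away
  yy <- seq(-0.27, 0.40, by = 0.025)   # platform edge at y = 0.33
  tr <- swim_trajectory(seq_along(yy) * 0.1 - 0.1, rep(0, length(yy)), yy, p)
  tm <- escape_latency(tr)
  expect_equal(tm$latency, 0.6 / 0.25, tolerance = 0.1)
  expect_false(tm$guided)
  expect_equal(tm$mean_velocity, tm$path_length / tm$latency,
               tolerance = 1e-9)

  # never reaches the platform
  t2 <- seq(0, 60, 0.1)
  tr2 <- swim_trajectory(t2, 0.5 * cos(t2), 0.5 * sin(t2), p)
  tm2 <- escape_latency(tr2)
  expect_equal(tm2$latency, 60)
  expect_true(tm2$guided)

  # first sample already on the platform: latency is one sample interval
  tr3 <- swim_trajectory(c(0, 0.1, 0.2), c(0, 0, 0), c(0.375, 0.38, 0.385), p)
  expect_equal(escape_latency(tr3)$latency, 0.1)

  prb <- swim_trajectory(c(0, 1), c(0, 0.1), c(0, 0), p,
                         meta = list(probe = TRUE))
  expect_error(escape_latency(prb), "mode error")
})

test_that("quadrants are compass sectors with a counterclockwise tie rule", {
  p <- pool_geometry()
  expect_identical(quadrant_of(0, 0.5, p), "N")
  expect_identical(quadrant_of(0.5, 0, p), "E")
  expect_identical(quadrant_of(-0.5, 0, p), "W")
  expect_identical(quadrant_of(0, -0.5, p), "S")
  expect_identical(quadrant_of(0.3, 0.3, p), "N")    # on the 45-degree line
  expect_identical(quadrant_of(-0.3, 0.3, p), "W")   # 135-degree line
  expect_error(quadrant_of(0.8, 0.8, p), "outside the pool")
})

test_that("quadrant distances conserve total path length exactly", {
  p <- pool_geometry()
  # path entirely in the north sector
  tr <- swim_trajectory(0:10 / 10, seq(-0.1, 0.1, length.out = 11),
                        rep(0.5, 11), p)
  qd <- quadrant_distances(tr)
  expect_equal(unname(qd$distances["N"]), qd$total)
  expect_equal(sum(qd$distances[c("S", "E", "W")]), 0)

  # full circle: four-fold symmetry gives four equal shares
  th <- seq(pi / 4, 2 * pi + pi / 4, length.out = 4 * 90 + 1)
  tr2 <- swim_trajectory(seq_along(th) / 100, 0.5 * cos(th), 0.5 * sin(th), p)
  qd2 <- quadrant_distances(tr2)
  expect_equal(max(qd2$distances) - min(qd2$distances), 0, tolerance = 1e-9)
  expect_equal(sum(qd2$distances), qd2$total, tolerance = 0)

  # conservation on rough random-walk paths
  for (s in 1:10) {
    tr3 <- simulate_swim_trial(p, bias_gain = 0.3, seed = s)
    qd3 <- quadrant_distances(tr3)
    expect_equal(sum(qd3$distances), path_length(tr3), tolerance = 1e-9)
  }
})

test_that("path length is robust to halving the sampling rate", {
  p <- pool_geometry()
  th <- seq(0, 3 * pi, length.out = 1201)
  x <- 0.4 * cos(th) * (1 - th / 20); y <- 0.4 * sin(th) * (1 - th / 20)
  full <- swim_trajectory(seq_along(th) / 100, x, y, p)
  half <- swim_trajectory(seq_along(th)[c(TRUE, FALSE)] / 100,
                          x[c(TRUE, FALSE)], y[c(TRUE, FALSE)], p)
  expect_lt(abs(path_length(half) - path_length(full)) / path_length(full),
            0.02)
})

test_that("simulated swims respect the pool, the clock and the bias limits", {
  p <- pool_geometry()
  expect_error(simulate_swim_trial(p, 1, speed = 10, dt = 0.1), "step-size")
  expect_error(simulate_swim_trial(p, -1), "bias_gain")
  for (s in 1:25) {
    tr <- simulate_swim_trial(p, bias_gain = stats::runif(1, 0, 2), seed = s)
    expect_true(all(tr$x^2 + tr$y^2 <= p$radius^2 * (1 + 1e-9)))
    expect_lte(escape_latency(tr)$latency, 60)
  }
  # infinite-bias limit: a straight approach from the far wall
  tr <- simulate_swim_trial(p, bias_gain = 1e9, start_angle = 3 * pi / 2,
                            seed = 1)
  tm <- escape_latency(tr)
  chord <- 0.75 + 0.375 - 0.045
  expect_lt(tm$path_length, 1.05 * chord)
  # zero bias: unbiased search mostly times out
  timeouts <- vapply(1:100, function(s) {
    escape_latency(simulate_swim_trial(p, 0, seed = s))$guided
  }, NA)
  expect_gt(mean(timeouts), 0.5)
})

test_that("probe trials with a strong remembered bias favour the N quadrant", {
  p <- pool_geometry()
  nmax <- vapply(1:50, function(s) {
    qd <- quadrant_distances(simulate_swim_trial(p, 1.5, probe = TRUE,
                                                 seed = s))
    names(which.max(qd$distances)) == "N"
  }, NA)
  expect_gt(mean(nmax), 0.5)
  tr <- simulate_swim_trial(p, 1.5, probe = TRUE, seed = 1)
  expect_equal(max(tr$t), 30)
})

test_that("trajectories round-trip through the text format", {
  tr <- simulate_swim_trial(pool_geometry(), 1, seed = 8,
                            meta = list(subject = "S1", day = 2L, trial = 3L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(back$x, tr$x)
  expect_identical(back$y, tr$y)
  expect_identical(back$meta$probe, FALSE)
  expect_identical(back$meta$day, 2L)
})
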
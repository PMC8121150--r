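# Sliding-window drowsiness detection.

idealThresholds <- function(rW = 1, channel = 1L) {
  sleepStageRadii(rW, channel = channel)
}

test_that("window means equal naive loop means and handle exclusions", {
  tr <- polarTrajectory(rep(7 * pi / 4, 6), rep(2, 6))
  m <- windowMeans(tr, c(1, 6))
  expect_equal(m$meanAngle, 7 * pi / 4)
  expect_equal(m$meanMagnitude, 2)

  tr2 <- polarTrajectory(c(3 * pi / 2, 7 * pi / 4), c(1, 1))
  expect_equal(windowMeans(tr2, c(1, 2))$meanAngle, 13 * pi / 8)

  set.seed(41)
  ang <- runif(50, 0, 2 * pi - 1e-9)
  mag <- runif(50, 0.1, 2)
  tr3 <- polarTrajectory(ang, mag)
  m3 <- windowMeans(tr3, c(11, 30))
  p <- trajectoryPoints(tr3)
  expect_equal(m3$meanAngle, sum(p$angle[11:30]) / 20, tolerance = 1e-12)
  expect_equal(m3$meanMagnitude, sum(p$magnitude[11:30]) / 20,
               tolerance = 1e-12)

  zero <- buildTrajectory(
    hemodynamicRecording(matrix(0, 5, 1), matrix(0, 5, 1), 1.81), 1)
  expect_error(windowMeans(zero, c(1, 5)), "undefined")
})

test_that("angle criterion gates the magnitude criterion", {
  th <- idealThresholds()
  expect_false(checkCriteria(list(meanAngle = pi / 2, meanMagnitude = 99), th))
  expect_true(checkCriteria(list(meanAngle = 7 * pi / 4,
                                 meanMagnitude = 1.2), th))
  expect_false(checkCriteria(list(meanAngle = 7 * pi / 4,
                                  meanMagnitude = 0.9), th))
  # strict bounds
  expect_false(checkCriteria(list(meanAngle = 3 * pi / 4,
                                  meanMagnitude = 2), th))
  expect_true(checkCriteria(list(meanAngle = 7 * pi / 4, meanMagnitude = 0.7),
                            th, circle = "N3"))
})

test_that("stationary wakefulness trajectories yield no events", {
  set.seed(42)
  n <- 400
  tr <- polarTrajectory(runif(n, pi / 2, pi), rnorm(n, 0.9, 0.05))
  expect_identical(nrow(detectDrowsiness(tr, idealThresholds())), 0L)
})

test_that("a constructed crossing is detected once, near the true onset", {
  cfg <- synthConfig(seed = 43, nChannels = 1)
  g <- generateTransitionRecording(cfg)
  tr <- buildTrajectory(g$recording, 1)
  ev <- detectDrowsiness(tr, g$thresholds[[1]])
  expect_identical(nrow(ev), 1L)
  w <- ceiling(5 * samplingRate(tr))
  expect_lte(abs(ev$onset_sample + 1L - g$truthOnsets[1]), w)
  expect_true(ev$phase_at_crossing %in% c(7L, 8L))
  expect_gt(ev$window_mean_magnitude, 1)
  expect_gt(ev$window_mean_angle, 3 * pi / 4)
})

test_that("magnitude capped below the W radius never fires", {
  n <- 300
  ang <- c(rep(3 * pi / 4, 100), seq(3 * pi / 4, 7 * pi / 4, length.out = 100),
           rep(7 * pi / 4, 100))
  tr <- polarTrajectory(ang, rep(0.8, n))
  expect_identical(nrow(detectDrowsiness(tr, idealThresholds())), 0L)
})

test_that("detection is translation-equivariant in time", {
  cfg <- synthConfig(seed = 44, nChannels = 1)
  g <- generateTransitionRecording(cfg)
  o <- hbo(g$recording)[, 1]
  r <- hbr(g$recording)[, 1]
  k <- 37L
  padO <- c(o[seq_len(k)] * 0 + 0.9 * cos(3 * pi / 4), o)
  padR <- c(r[seq_len(k)] * 0 + 0.9 * sin(3 * pi / 4), r)
  tr1 <- buildTrajectory(hemodynamicRecording(matrix(o), matrix(r), 1.81), 1)
  tr2 <- buildTrajectory(hemodynamicRecording(matrix(padO), matrix(padR),
                                              1.81), 1)
  e1 <- detectDrowsiness(tr1, idealThresholds())
  e2 <- detectDrowsiness(tr2, idealThresholds())
  expect_identical(nrow(e1), nrow(e2))
  expect_identical(e2$onset_sample, e1$onset_sample + k)
})

test_that("emitted events always satisfy the window criteria", {
  for (seed in 45:48) {
    cfg <- synthConfig(seed = seed, nChannels = 1)
    g <- generateTransitionRecording(cfg, nTransitions = 2L)
    ev <- detectDrowsiness(buildTrajectory(g$recording, 1),
                           g$thresholds[[1]])
    if (nrow(ev)) {
      expect_true(all(ev$window_mean_angle > 3 * pi / 4 &
                        ev$window_mean_angle < 2 * pi))
      expect_true(all(ev$window_mean_magnitude > 1))
      expect_true(all(ev$phase_at_crossing %in% c(7L, 8L)))
    }
  }
})

test_that("two sequential transitions give two ordered events", {
  cfg <- synthConfig(seed = 49, nChannels = 1)
  g <- generateTransitionRecording(cfg, nTransitions = 2L)
  expect_length(g$truthOnsets, 2L)
  ev <- detectDrowsiness(buildTrajectory(g$recording, 1), g$thresholds[[1]])
  expect_gte(nrow(ev), 2L)
  expect_true(all(diff(ev$onset_sample) > 0))
})

test_that("channels rank by event count with earliest-onset tie-break", {
  ev <- data.frame(channel = c(8, 8, 8, 2),
                   onset_time = c(10, 20, 30, 5))
  expect_identical(activeChannels(ev), c(8L, 2L))
  expect_identical(activeChannels(ev[0, ]), integer())
  tie <- data.frame(channel = c(1, 1, 5, 5),
                    onset_time = c(10, 40, 7, 50))
  expect_identical(activeChannels(tie), c(5L, 1L))
})

test_that("uncalibrated channel mismatch is a configuration error", {
  tr <- polarTrajectory(rep(pi, 20), rep(1, 20))
  expect_error(detectDrowsiness(tr, idealThresholds(channel = 3L)),
               "channel")
})
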
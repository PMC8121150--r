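# Synthetic CORE-geometry generator.

test_that("noise-free stage draws sit exactly on the stage circle", {
  cfg <- synthConfig(seed = 71, nChannels = 1, radialNoiseSd = 0,
                     whiteNoiseSd = 0,
                     physio = list(none = c(0.1, 0)),
                     stagePlan = data.frame(stage = "N2",
                                            duration_s = 100 / 1.81))
  sim <- generateStageRecording(cfg)
  tr <- trajectoryPoints(buildTrajectory(sim$recording, 1))
  expect_equal(tr$magnitude, rep(0.8077, nrow(tr)), tolerance = 1e-9)
  expect_true(all(tr$phase %in% c(7L, 8L)))
})

test_that("wakefulness samples live in phases 3-4, NREM in 7-8", {
  cfg <- synthConfig(seed = 72, nChannels = 2)
  sim <- generateStageRecording(cfg)
  tr <- trajectoryPoints(buildTrajectory(sim$recording, 1))
  wake <- sim$labels == "W"
  expect_gt(mean(tr$phase[wake] %in% c(3L, 4L)), 0.95)
  expect_gt(mean(tr$phase[!wake] %in% c(7L, 8L)), 0.95)
})

test_that("generation is bitwise deterministic under a fixed seed", {
  cfg <- synthConfig(seed = 73)
  a <- generateStageRecording(cfg)
  b <- generateStageRecording(cfg)
  expect_identical(hbo(a$recording), hbo(b$recording))
  expect_identical(hbr(a$recording), hbr(b$recording))
  g1 <- generateTransitionRecording(cfg)
  g2 <- generateTransitionRecording(cfg)
  expect_identical(hbo(g1$recording), hbo(g2$recording))
  expect_identical(g1$truthOnsets, g2$truthOnsets)
})

test_that("mean-magnitude ratios recover the stage coefficients", {
  cfg <- synthConfig(seed = 74, nChannels = 1)
  sim <- generateStageRecording(cfg)
  tr <- trajectoryPoints(buildTrajectory(sim$recording, 1))
  means <- tapply(tr$magnitude, sim$labels, mean)
  ratios <- means[c("N1", "N2", "N3")] / means[["W"]]
  expect_equal(as.numeric(ratios), unname(stageCoefficients()),
               tolerance = 0.02)
})

test_that("transition ground truth matches the detection predicate", {
  cfg <- synthConfig(seed = 75, nChannels = 1, radialNoiseSd = 0,
                     whiteNoiseSd = 0, physio = list(none = c(0.1, 0)))
  g <- generateTransitionRecording(cfg)
  expect_length(g$truthOnsets, 1L)
  ev <- detectDrowsiness(buildTrajectory(g$recording, 1), g$thresholds[[1]])
  # noiseless: detector onset equals the brute-force onset exactly
  expect_identical(ev$onset_sample + 1L, g$truthOnsets)
})

test_that("a capped transition never reaches the W circle", {
  cfg <- synthConfig(seed = 76, nChannels = 1, baseRadius = 1)
  g <- generateTransitionRecording(cfg)
  rec <- g$recording
  # cap the magnitude at 0.8 rW while keeping angles
  tr <- trajectoryPoints(buildTrajectory(rec, 1))
  scale <- pmin(1, 0.8 / pmax(tr$magnitude, 1e-12))
  capped <- hemodynamicRecording(matrix(tr$hbo * scale),
                                 matrix(tr$hbr * scale), samplingRate(rec))
  ev <- detectDrowsiness(buildTrajectory(capped, 1), g$thresholds[[1]])
  expect_identical(nrow(ev), 0L)
})

test_that("raw-intensity forward model round-trips through the inversion", {
  cfg <- synthConfig(seed = 77, nChannels = 2,
                     stagePlan = data.frame(stage = c("W", "N1"),
                                            duration_s = 60))
  sim <- generateStageRecording(cfg)
  params <- mbllParameters()
  raw <- generateRawIntensity(sim$recording, params)
  rec <- rawToHemodynamic(raw, params)
  nPad <- floor(params$baselineSeconds * samplingRate(raw))
  got <- hbo(rec)[-seq_len(nPad), , drop = FALSE]
  expect_equal(got, hbo(sim$recording), tolerance = 1e-9,
               ignore_attr = TRUE)
  gotR <- hbr(rec)[-seq_len(nPad), , drop = FALSE]
  expect_equal(gotR, hbr(sim$recording), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zero hemodynamics give constant intensities; scaling is linear", {
  z <- hemodynamicRecording(matrix(0, 20, 1), matrix(0, 20, 1), 1.81)
  raw <- generateRawIntensity(z)
  expect_equal(max(intensityBlock(raw, 1)) - min(intensityBlock(raw, 1)), 0)

  cfg <- synthConfig(seed = 78, nChannels = 1,
                     stagePlan = data.frame(stage = "W", duration_s = 40))
  sim <- generateStageRecording(cfg)
  params <- mbllParameters()
  doubled <- hemodynamicRecording(2 * hbo(sim$recording),
                                  2 * hbr(sim$recording), 1.81)
  r1 <- rawToHemodynamic(generateRawIntensity(sim$recording, params), params)
  r2 <- rawToHemodynamic(generateRawIntensity(doubled, params), params)
  expect_equal(hbo(r2), 2 * hbo(r1), tolerance = 1e-8)
})
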
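# Modified Beer-Lambert conversion: OD referencing and the 2x2 inversion.

mkRaw <- function(i1, i2, fs = 10) {
  rawRecording(i1, i2, fs, wavelengths = c(760, 830))
}

test_that("constant intensities give zero optical-density change", {
  rec <- mkRaw(matrix(5, 40, 1), matrix(2, 40, 1))
  od <- intensityToOD(rec)
  expect_equal(od$od[[1]], matrix(0, 40, 1), ignore_attr = TRUE)
  expect_equal(od$od[[2]], matrix(0, 40, 1), ignore_attr = TRUE)
})

test_that("a halved intensity yields dA = ln 2 at that sample", {
  i1 <- matrix(4, 50, 1)
  i1[45] <- 2  # outside the 3-sample baseline at fs = 10 (first 30 s)
  rec <- mkRaw(i1, matrix(1, 50, 1), fs = 0.1)
  od <- intensityToOD(rec, baselineWindow = c(1, 3))
  expect_equal(od$od[[1]][45], log(2), tolerance = 1e-12)
})

test_that("forward model I = Iref * exp(-x) is recovered exactly", {
  set.seed(11)
  x <- matrix(rnorm(60, sd = 0.1), 30, 2)
  rec <- mkRaw(1000 * exp(-x), 500 * exp(-2 * x))
  od <- intensityToOD(rec, baselineWindow = c(1, 30))
  # referencing is against the mean intensity, not the mean exponent
  ref1 <- colMeans(1000 * exp(-x))
  expected <- log(rep(ref1, each = 30) / (1000 * exp(-x)))
  expect_equal(od$od[[1]], expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("non-positive intensities are rejected with location info", {
  i1 <- matrix(1, 10, 1); i1[7] <- 0
  expect_error(intensityToOD(mkRaw(i1, matrix(1, 10, 1))),
               "sample 7, channel 1")
})

test_that("identity extinction with unit pathlength is a passthrough", {
  od <- list(od = list(matrix(1:6 / 10, 3), matrix(6:1 / 10, 3)),
             samplingRate = 1.81, subject = "t", channelLabels = NULL,
             time = numeric())
  p <- mbllParameters(extinction = diag(2), distance = 1, dpf = 1)
  rec <- odToConcentrations(od, p)
  expect_equal(hbo(rec), od$od[[1]], ignore_attr = TRUE)
  expect_equal(hbr(rec), od$od[[2]], ignore_attr = TRUE)
})

test_that("zero OD maps to zero concentrations", {
  od <- list(od = list(matrix(0, 5, 1), matrix(0, 5, 1)),
             samplingRate = 2, subject = "t", channelLabels = NULL,
             time = numeric())
  rec <- odToConcentrations(od)
  expect_true(all(hbo(rec) == 0) && all(hbr(rec) == 0))
})

test_that("forward-inverse round trip recovers concentrations", {
  set.seed(12)
  p <- mbllParameters()
  hboTrue <- matrix(rnorm(200, sd = 0.5), 100, 2)
  hbrTrue <- matrix(rnorm(200, sd = 0.3), 100, 2)
  E <- p$extinction
  ld <- p$distance * p$dpf
  a1 <- (E[1, 1] * hboTrue + E[1, 2] * hbrTrue) * ld[1]
  a2 <- (E[2, 1] * hboTrue + E[2, 2] * hbrTrue) * ld[2]
  od <- list(od = list(a1, a2), samplingRate = 1.81, subject = "t",
             channelLabels = NULL, time = numeric())
  rec <- odToConcentrations(od, p)
  expect_equal(hbo(rec), hboTrue, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(hbr(rec), hbrTrue, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the inversion is linear in the OD input", {
  set.seed(13)
  p <- mbllParameters()
  mk <- function(a1, a2) list(od = list(a1, a2), samplingRate = 1,
                              subject = "t", channelLabels = NULL,
                              time = numeric())
  a <- matrix(rnorm(20), 10, 2); b <- matrix(rnorm(20), 10, 2)
  r1 <- odToConcentrations(mk(a, b), p)
  r2 <- odToConcentrations(mk(2 * a, 2 * b), p)
  r3 <- odToConcentrations(mk(3 * a, 3 * b), p)
  expect_equal(hbo(r1) * 2, hbo(r2), tolerance = 1e-10)
  expect_equal(hbo(r1) + hbo(r2), hbo(r3), tolerance = 1e-10)
})

test_that("singular extinction matrices are refused", {
  expect_error(mbllParameters(extinction = matrix(c(1, 2, 2, 4), 2)),
               "singular")
})

test_that("round trips hold for random well-conditioned parameter sets", {
  set.seed(14)
  for (k in 1:10) {
    repeat {
      E <- matrix(runif(4, 1e-4, 2e-3), 2)
      if (kappa(E) < 1e6 && abs(det(E)) > 1e-12) break
    }
    p <- mbllParameters(extinction = E, distance = runif(1, 1, 4),
                        dpf = runif(2, 3, 8))
    hboTrue <- matrix(rnorm(30), 30, 1)
    hbrTrue <- matrix(rnorm(30), 30, 1)
    ld <- p$distance * p$dpf
    od <- list(od = list((E[1, 1] * hboTrue + E[1, 2] * hbrTrue) * ld[1],
                         (E[2, 1] * hboTrue + E[2, 2] * hbrTrue) * ld[2]),
               samplingRate = 1, subject = "t", channelLabels = NULL,
               time = numeric())
    rec <- odToConcentrations(od, p)
    expect_equal(hbo(rec), hboTrue, tolerance = 1e-8, ignore_attr = TRUE)
  }
})
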
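# Windowed slope/peak features and min-max rescaling.

test_that("trajectory slope divides by the window length N", {
  expect_identical(trajectorySlope(c(5, 5, 5)), 0)
  expect_equal(trajectorySlope(0:8), 8 / 9, tolerance = 1e-12)
  x <- c(0.3, 1.7, -0.2, 4.4)
  expect_equal(trajectorySlope(rev(x)), -trajectorySlope(x),
               tolerance = 1e-12)
  expect_error(trajectorySlope(1), "at least 2")
  expect_equal(trajectorySlope(0:8, perSecond = TRUE, samplingRate = 2),
               2 * 8 / 9, tolerance = 1e-12)
})

test_that("window statistics enumerate strict interior local maxima", {
  st <- windowStats(c(0, 2, 1, 3, 0))
  expect_equal(st$M, 1.2)
  expect_identical(st$peaks, c(2L, 4L))
  expect_equal(st$P, 3)
  expect_equal(st$SoP, 5)

  expect_message(mono <- windowStats(c(1, 2, 3, 4)), "no interior")
  expect_equal(mono$P, 4)
  expect_equal(mono$SoP, 0)

  expect_message(konst <- windowStats(rep(2, 5)), "no interior")
  expect_equal(konst$M, 2)
  expect_equal(konst$P, 2)
  expect_equal(konst$SoP, 0)
  expect_error(windowStats(numeric()), "empty")
})

test_that("plateau peaks count once, at the plateau's first sample", {
  expect_identical(localMaxima(c(0, 1, 1, 0)), 2L)
  expect_identical(localMaxima(c(0, 1, 1, 2)), integer())
  expect_identical(localMaxima(c(2, 1, 1, 0)), integer())
  expect_identical(localMaxima(c(0, 3, 0, 3, 3, 0)), c(2L, 4L))
})

test_that("SoP is at least P whenever a local maximum exists", {
  set.seed(51)
  for (k in 1:50) {
    x <- rnorm(20)
    st <- suppressMessages(windowStats(x))
    if (length(st$peaks)) expect_gte(st$SoP, st$P)
  }
})

test_that("extracted features match closed-form values on a ramp", {
  n <- 10
  o <- seq(0, 0.9, length.out = n)   # linear HbO ramp
  r <- rep(1, n)
  rec <- hemodynamicRecording(matrix(o), matrix(r), 2)
  tr <- buildTrajectory(rec, 1)
  ft <- extractFeatures(tr, data.frame(start = 1, end = n, label = "W"))
  f <- featureMatrix(ft)
  expect_equal(unname(f[1, "m_hbo"]), (o[n] - o[1]) / n, tolerance = 1e-12)
  expect_equal(unname(f[1, "m_hbr"]), 0)
  expect_equal(unname(f[1, "m_hbt"]), (o[n] - o[1]) / n, tolerance = 1e-12)
  expect_equal(unname(f[1, "m_coe"]), -(o[n] - o[1]) / n, tolerance = 1e-12)
  expect_equal(unname(f[1, "mean_hbo"]), mean(o), tolerance = 1e-12)
  expect_identical(unname(f[1, "sop_hbo"]), 0)  # monotone fallback
  expect_identical(nrow(f), 1L)
  expect_identical(ncol(f), 9L)
})

test_that("feature extraction rejects bad windows and empty input works", {
  tr <- polarTrajectory(runif(20, 0, 3), runif(20, 0.5, 1))
  expect_error(extractFeatures(tr, data.frame(start = 1, end = 10,
                                              label = "NAP")),
               "label")
  empty <- extractFeatures(tr, data.frame(start = integer(),
                                          end = integer(),
                                          label = character()))
  expect_identical(nrow(featureMatrix(empty)), 0L)
})

test_that("slope features are shift-invariant while the mean shifts", {
  set.seed(52)
  ang <- runif(30, 0.2, 1.2)
  rad <- runif(30, 0.5, 1.5)
  tr1 <- polarTrajectory(ang, rad)
  p <- trajectoryPoints(tr1)
  rec2 <- hemodynamicRecording(matrix(p$hbo + 5), matrix(p$hbr), 1.81)
  tr2 <- buildTrajectory(rec2, 1)
  w <- data.frame(start = 1, end = 30, label = "W")
  f1 <- featureMatrix(extractFeatures(tr1, w))
  f2 <- featureMatrix(extractFeatures(tr2, w))
  expect_equal(f2[1, "m_hbo"], f1[1, "m_hbo"], tolerance = 1e-10)
  expect_equal(f2[1, "m_hbr"], f1[1, "m_hbr"], tolerance = 1e-10)
  expect_equal(f2[1, "mean_hbo"], f1[1, "mean_hbo"] + 5, tolerance = 1e-10)
})

test_that("angle tracks are unwrapped before the slope", {
  ang <- c(6.2, 6.25, 0.02, 0.07)  # crosses the 2*pi wrap
  tr <- polarTrajectory(ang, rep(1, 4))
  f <- featureMatrix(extractFeatures(
    tr, data.frame(start = 1, end = 4, label = "N1")))
  un <- unwrapAngles(ang)
  expect_equal(unname(f[1, "m_angle"]), (un[4] - un[1]) / 4, tolerance = 1e-9)
  expect_lt(abs(f[1, "m_angle"]), 0.1)  # no fake -2*pi jump
})

test_that("min-max rescaling hits the bounds and round-trips", {
  mkTab <- function(col) {
    f <- as.data.frame(matrix(rep(col, 9), length(col), 9))
    names(f) <- colnames(featureMatrix(separableFeatureTable(2)))
    f[[2]] <- f[[2]] * 2 + 1  # make columns distinct
    new("FeatureTable", features = f,
        label = factor(rep("W", length(col)),
                       levels = c("W", "N1", "N2", "N3")),
        channel = rep(1L, length(col)), window = seq_along(col),
        scaled = FALSE, scaling = data.frame())
  }
  sc <- minmaxRescale(mkTab(c(0, 5, 10)))
  expect_equal(unname(featureMatrix(sc)[, 1]), c(-1, 0, 1))
  expect_equal(unname(featureMatrix(minmaxRescale(mkTab(c(-3, 3))))[, 1]),
               c(-1, 1))

  set.seed(53)
  tab <- separableFeatureTable(20)
  sc1 <- minmaxRescale(tab)
  expect_true(all(featureMatrix(sc1) >= -1 & featureMatrix(sc1) <= 1))
  expect_equal(apply(featureMatrix(sc1), 2, min), setNames(rep(-1, 9),
               colnames(featureMatrix(sc1))), tolerance = 1e-12)
  expect_equal(unname(apply(featureMatrix(sc1), 2, max)), rep(1, 9),
               tolerance = 1e-12)
  # reusing the stored map reproduces the output; inverse recovers input
  sc2 <- minmaxRescale(tab, scaling = sc1@scaling)
  expect_equal(featureMatrix(sc2), featureMatrix(sc1), tolerance = 1e-12)
  s <- sc1@scaling
  back <- sweep(sweep((featureMatrix(sc1) + 1) / 2, 2, s$max - s$min, "*"),
                2, s$min, "+")
  expect_equal(back, featureMatrix(tab), tolerance = 1e-12)
})

test_that("constant feature columns are a degenerate-scale error", {
  tab <- separableFeatureTable(5)
  tab@features$peak_hbo <- 1
  expect_error(minmaxRescale(tab), "peak_hbo")
})
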
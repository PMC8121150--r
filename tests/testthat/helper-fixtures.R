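# Shared fixtures, built in code at test time.

# tiny hemodynamic recording with deterministic values
tinyRecording <- function(n = 10, channels = 2, fs = 1.81, seed = 42) {
  set.seed(seed)
  hemodynamicRecording(hbo = matrix(rnorm(n * channels), n),
                       hbr = matrix(rnorm(n * channels), n),
                       samplingRate = fs, subject = "fixture")
}

# trajectory with prescribed polar coordinates on one channel
polarTrajectory <- function(angles, radii, fs = 1.81) {
  rec <- hemodynamicRecording(hbo = radii * cos(angles),
                              hbr = radii * sin(angles),
                              samplingRate = fs)
  buildTrajectory(rec, 1)
}

# independent octant classifier built purely from the tabulated
# sign/inequality patterns of the eight phases (the oracle for
# classifyPhase; deliberately not angle-based)
signPatternOctant <- function(hbo, hbr) {
  hbt <- hbo + hbr
  coe <- hbr - hbo
  n <- length(hbo)
  out <- integer(n)
  for (i in seq_len(n)) {
    o <- hbo[i]; r <- hbr[i]; t <- hbt[i]; c <- coe[i]
    out[i] <-
      if (o > 0 && r > 0 && t > 0 && c < 0 && o > r) 1L
      else if (o > 0 && r > 0 && t > 0 && c > 0 && o < r && t > c) 2L
      else if (o < 0 && r > 0 && t > 0 && c > 0 && t < c) 3L
      else if (o < 0 && r > 0 && t < 0 && c > 0) 4L
      else if (o < 0 && r < 0 && t < 0 && c > 0 && o < r) 5L
      else if (o < 0 && r < 0 && t < 0 && c < 0 && o > r && t < c) 6L
      else if (o > 0 && r < 0 && t < 0 && c < 0 && t > c) 7L
      # the eighth pattern's inequality is a magnitude comparison: with
      # t > 0 and c < 0 the signed form would be unsatisfiable
      else if (o > 0 && r < 0 && t > 0 && c < 0 && abs(t) < abs(c)) 8L
      else NA_integer_  # on a sector boundary
  }
  out
}

# well-separated 4-class Gaussian clusters in a chosen feature pair,
# embedded in a full 9-feature table
separableFeatureTable <- function(nPerClass = 100, sdWithin = 1,
                                  separation = 8, seed = 7) {
  set.seed(seed)
  centers <- separation * sdWithin *
    cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  n <- 4 * nPerClass
  f <- as.data.frame(matrix(rnorm(n * 9), n))
  names(f) <- c("m_hbo", "m_hbr", "m_hbt", "m_coe", "m_angle", "m_mag",
                "mean_hbo", "peak_hbo", "sop_hbo")
  lab <- rep(c("W", "N1", "N2", "N3"), each = nPerClass)
  for (k in 1:4) {
    i <- seq_len(nPerClass) + (k - 1) * nPerClass
    f$m_angle[i] <- rnorm(nPerClass, centers[k, 1], sdWithin)
    f$m_mag[i] <- rnorm(nPerClass, centers[k, 2], sdWithin)
  }
  new("FeatureTable", features = f,
      label = factor(lab, levels = c("W", "N1", "N2", "N3")),
      channel = rep(1L, n), window = seq_len(n),
      scaled = FALSE, scaling = data.frame())
}
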
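#' @include AllClasses.R recording.R
#' @importFrom signal butter filtfilt
NULL

#' Default physiological stop bands
#'
#' Respiration (0.3-0.4 Hz), cardiac (1-1.2 Hz) and the slow-drift band
#' below 0.01 Hz, the latter applied as a high-pass at 0.01 Hz (encoded as
#' a stop band with lower edge 0).
#'
#' @return list of length-2 numeric vectors (low, high) in Hz.
#' @export
defaultStopBands <- function() {
  list(respiration = c(0.3, 0.4), cardiac = c(1, 1.2),
       drift = c(0, 0.01))
}

.applyColumns <- function(m, f) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- f(m[, j])
  out
}

.mapAssays <- function(rec, f) {
  for (nm in assayNames(rec)) {
    SummarizedExperiment::assay(rec, nm) <- .applyColumns(assay(rec, nm), f)
  }
  rec
}

#' Band rejection of physiological interference
#'
#' Zero-phase (forward-backward) Butterworth filtering applied per channel
#' and per assay. Each stop band (low, high) becomes a band-stop of order 4;
#' a band with lower edge 0 becomes a high-pass at its upper edge (order 2).
#' Bands lying wholly at or above Nyquist are skipped with a warning — at
#' the 1.81 Hz sampling rate typical of the target instrument the 1-1.2 Hz
#' cardiac band cannot be rejected and is reported as skipped. Bands
#' straddling Nyquist are clipped to 99% of Nyquist, with a warning.
#'
#' @param rec a [FnirsRecording-class] (any kind) or numeric matrix.
#' @param bands list of length-2 (low, high) vectors in Hz with low < high;
#'   defaults to [defaultStopBands()].
#' @param samplingRate required when `rec` is a bare matrix.
#' @return the filtered object, same class as `rec`.
#' @export
bandReject <- function(rec, bands = defaultStopBands(), samplingRate = NULL) {
  if (is(rec, "FnirsRecording")) {
    fs <- samplingRate(rec)
    return(.mapAssays(rec, function(x) .bandRejectVector(x, bands, fs)))
  }
  stopifnot(is.numeric(rec), !is.null(samplingRate))
  m <- as.matrix(rec)
  .applyColumns(m, function(x) .bandRejectVector(x, bands, samplingRate))
}

.bandRejectVector <- function(x, bands, fs) {
  nyq <- fs / 2
  for (b in bands) {
    stopifnot(length(b) == 2L)
    if (b[1] >= b[2]) stop("stop band must have low < high")
    if (b[1] >= nyq) {
      warning(sprintf(
        "stop band %.3g-%.3g Hz is at/above Nyquist (%.3g Hz); skipped",
        b[1], b[2], nyq))
      next
    }
    hi <- b[2]
    if (hi >= nyq) {
      hi <- 0.99 * nyq
      warning(sprintf(
        "stop band %.3g-%.3g Hz clipped to %.3g-%.3g Hz (Nyquist %.3g Hz)",
        b[1], b[2], b[1], hi, nyq))
    }
    if (b[1] <= 0) {
      flt <- signal::butter(2, hi / nyq, type = "high")
    } else {
      flt <- signal::butter(2, c(b[1], hi) / nyq, type = "stop")
    }
    x <- signal::filtfilt(flt, x)
  }
  x
}

#' Gaussian smoothing
#'
#' Convolution with a unit-area Gaussian kernel truncated at +/- 4 sigma,
#' reflect-padded at the edges; `sigmaSeconds = 0` is the identity.
#'
#' @param rec a [FnirsRecording-class] or numeric matrix/vector.
#' @param sigmaSeconds kernel standard deviation in seconds (>= 0).
#' @param samplingRate required when `rec` is a bare matrix/vector.
#' @return the smoothed object, same class as `rec`.
#' @export
gaussianSmooth <- function(rec, sigmaSeconds, samplingRate = NULL) {
  stopifnot(length(sigmaSeconds) == 1L, sigmaSeconds >= 0)
  if (is(rec, "FnirsRecording")) {
    fs <- samplingRate(rec)
    return(.mapAssays(rec, function(x) .gaussVector(x, sigmaSeconds * fs)))
  }
  stopifnot(is.numeric(rec), !is.null(samplingRate))
  if (is.null(dim(rec))) {
    return(.gaussVector(rec, sigmaSeconds * samplingRate))
  }
  .applyColumns(as.matrix(rec),
                function(x) .gaussVector(x, sigmaSeconds * samplingRate))
}

#' @rdname gaussianSmooth
#' @param sigmaSamples kernel standard deviation in samples.
#' @export
gaussianKernel <- function(sigmaSamples) {
  stopifnot(sigmaSamples >= 0)
  if (sigmaSamples == 0) return(1)
  half <- max(1L, ceiling(4 * sigmaSamples))
  k <- exp(-0.5 * ((-half:half) / sigmaSamples)^2)
  k / sum(k)
}

.gaussVector <- function(x, sigmaSamples) {
  if (sigmaSamples == 0) return(x)
  k <- gaussianKernel(sigmaSamples)
  half <- (length(k) - 1L) / 2L
  n <- length(x)
  # reflect padding (no repeated edge sample)
  pad <- min(half, n - 1L)
  left <- x[(pad + 1L):2L]
  right <- x[n - (1:pad)]
  xp <- c(left, x, right)
  if (pad < half) {  # very short series: extend by edge replication
    xp <- c(rep(xp[1], half - pad), xp, rep(xp[length(xp)], half - pad))
  }
  stats::convolve(xp, rev(k), type = "filter")
}

#' Standard preprocessing chain
#'
#' Gaussian smoothing followed by band rejection, the order used upstream
#' of trajectory building and calibration.
#'
#' @param rec a hemodynamic [FnirsRecording-class].
#' @param sigmaSeconds Gaussian sigma in seconds; the default is 1.5
#'   samples at the recording's rate.
#' @param bands stop bands for [bandReject()].
#' @return the preprocessed recording.
#' @export
preprocessRecording <- function(rec, sigmaSeconds = NULL,
                                bands = defaultStopBands()) {
  if (is.null(sigmaSeconds)) sigmaSeconds <- 1.5 / samplingRate(rec)
  bandReject(gaussianSmooth(rec, sigmaSeconds), bands)
}
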
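#' @include AllClasses.R AllGenerics.R thresholds.R
NULL

.ANGLE_LOW_DEFAULT <- 3 * pi / 4

#' Window means of trajectory angle and magnitude
#'
#' Arithmetic means of the per-sample angle (taken in [0, 2*pi)) and
#' magnitude over a sample window. Zero-vector samples (undefined angle)
#' are excluded from both means, reducing n; a window with no defined
#' sample is an error. A circular (resultant-vector) angle mean is
#' available for windows that straddle the 2*pi wrap.
#'
#' @param traj a [VpaTrajectory-class].
#' @param window length-2 integer (first, last) 1-based sample indices.
#' @param circular use the circular mean of angles instead of the
#'   arithmetic mean (default FALSE, matching the detection criteria,
#'   whose sector does not straddle the wrap).
#' @return list with meanAngle, meanMagnitude and n (samples used).
#' @export
windowMeans <- function(traj, window, circular = FALSE) {
  p <- trajectoryPoints(traj)
  stopifnot(length(window) == 2L, window[1] >= 1L,
            window[2] <= nrow(p), window[1] <= window[2])
  i <- seq.int(window[1], window[2])
  ok <- !is.na(p$angle[i])
  if (!any(ok)) stop("window contains only zero-vector (undefined) samples")
  if (!all(ok)) {
    message(sprintf("window [%d,%d]: %d undefined sample(s) excluded",
                    window[1], window[2], sum(!ok)))
  }
  i <- i[ok]
  ma <- if (circular) {
    a <- atan2(mean(sin(p$angle[i])), mean(cos(p$angle[i])))
    if (a < 0) a + 2 * pi else a
  } else {
    mean(p$angle[i])
  }
  list(meanAngle = ma, meanMagnitude = mean(p$magnitude[i]), n = length(i))
}

#' Drowsiness angle and magnitude criteria
#'
#' The angle criterion requires the window mean angle to lie strictly in
#' (3*pi/4, 2*pi); it is evaluated first and must hold before the
#' magnitude criterion — window mean magnitude strictly above the chosen
#' threshold circle's radius — is considered.
#'
#' @param means result of [windowMeans()].
#' @param thresholds a [ThresholdSet-class].
#' @param circle which circle's radius to compare against
#'   (`"W"`, `"N1"`, `"N2"`, `"N3"`).
#' @param angleLow lower bound of the angle sector (default 3*pi/4).
#' @return logical scalar.
#' @export
checkCriteria <- function(means, thresholds, circle = "W",
                          angleLow = .ANGLE_LOW_DEFAULT) {
  stopifnot(is(thresholds, "ThresholdSet"), circle %in% .STAGES)
  if (!(means$meanAngle > angleLow && means$meanAngle < 2 * pi)) {
    return(FALSE)
  }
  means$meanMagnitude > thresholdRadii(thresholds)[[circle]]
}

#' @describeIn detectDrowsiness slides a window of
#'   `ceiling(windowSeconds * fs)` samples one sample at a time. A decision
#'   sample (the window's last sample) is *active* when (a) the window
#'   means satisfy the angle and magnitude criteria against the W circle
#'   and (b) the instantaneous point at that sample is in octant phase 7
#'   or 8 with |R| above the W radius. Maximal runs of active samples are
#'   reported as one event each, by onset. The `crossed_circle` column is
#'   a stage-grading extension: the innermost circle whose radius the
#'   onset window mean magnitude exceeds (under the printed magnitude
#'   criterion, which compares against the W radius, this is N3 whenever
#'   an event exists).
#' @param windowSeconds window width in seconds (default 5).
#' @param angleLow lower bound of the angle sector (default 3*pi/4).
#' @param circular use circular angle means (see [windowMeans()]).
#' @return data.frame with columns channel, onset_sample (0-based),
#'   onset_time, window_mean_angle, window_mean_magnitude, crossed_circle,
#'   phase_at_crossing, duration_samples.
#' @export
setMethod("detectDrowsiness", "VpaTrajectory",
          function(x, thresholds, windowSeconds = 5,
                   angleLow = .ANGLE_LOW_DEFAULT, circular = FALSE, ...) {
  stopifnot(is(thresholds, "ThresholdSet"))
  if (thresholds@channel != x@channel) {
    stop(sprintf("thresholds calibrated for channel %d, trajectory is %d",
                 thresholds@channel, x@channel))
  }
  p <- trajectoryPoints(x)
  n <- nrow(p)
  w <- ceiling(windowSeconds * samplingRate(x))
  empty <- data.frame(channel = integer(), onset_sample = integer(),
                      onset_time = numeric(), window_mean_angle = numeric(),
                      window_mean_magnitude = numeric(),
                      crossed_circle = character(),
                      phase_at_crossing = integer(),
                      duration_samples = integer())
  if (n < w) return(empty)
  rW <- thresholds@rW
  radii <- thresholdRadii(thresholds)

  ok <- !is.na(p$angle)
  angSum <- cumsum(ifelse(ok, p$angle, 0))
  magSum <- cumsum(ifelse(ok, p$magnitude, 0))
  sinSum <- cumsum(ifelse(ok, sin(p$angle), 0))
  cosSum <- cumsum(ifelse(ok, cos(p$angle), 0))
  okSum <- cumsum(as.numeric(ok))
  winSum <- function(s, i) s[i] - c(0, s)[i - w + 1L]

  i <- seq.int(w, n)
  nOk <- winSum(okSum, i)
  meanMag <- ifelse(nOk > 0, winSum(magSum, i) / nOk, NA_real_)
  meanAng <- if (circular) {
    a <- atan2(winSum(sinSum, i) / pmax(nOk, 1),
               winSum(cosSum, i) / pmax(nOk, 1))
    ifelse(a < 0, a + 2 * pi, a)
  } else {
    ifelse(nOk > 0, winSum(angSum, i) / nOk, NA_real_)
  }
  windowCrit <- !is.na(meanAng) & meanAng > angleLow & meanAng < 2 * pi &
    meanMag > rW
  instCrit <- !is.na(p$phase[i]) & p$phase[i] %in% c(7L, 8L) &
    p$magnitude[i] > rW
  active <- windowCrit & instCrit

  if (!any(active)) return(empty)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ev <- lapply(runs, function(k) {
    j <- starts[k]               # index into the decision-sample vector
    s <- i[j]                    # absolute (1-based) onset sample
    crossed <- names(radii)[max(which(radii < meanMag[j]))]
    stopifnot(meanAng[j] > angleLow, meanAng[j] < 2 * pi,
              meanMag[j] > radii[[crossed]],
              p$phase[s] %in% c(7L, 8L))
    data.frame(channel = x@channel, onset_sample = s - 1L,
               onset_time = p$time_s[s], window_mean_angle = meanAng[j],
               window_mean_magnitude = meanMag[j],
               crossed_circle = crossed,
               phase_at_crossing = p$phase[s],
               duration_samples = r$lengths[k])
  })
  do.call(rbind, ev)
})

#' Rank channels by detection activity
#'
#' Channels with more detection events rank first; ties are broken by the
#' earliest event onset time.
#'
#' @param events a data.frame of detection events (possibly row-bound from
#'   several channels), or a list of such data.frames.
#' @return integer vector of channel numbers, most active first (empty
#'   when there are no events).
#' @export
activeChannels <- function(events) {
  if (is.list(events) && !is.data.frame(events)) {
    events <- do.call(rbind, events)
  }
  if (is.null(events) || nrow(events) == 0L) return(integer())
  counts <- tapply(events$onset_time, events$channel, length)
  first <- tapply(events$onset_time, events$channel, min)
  ch <- as.integer(names(counts))
  ch[order(-as.integer(counts), as.numeric(first))]
}
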
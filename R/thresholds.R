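#' @include AllClasses.R AllGenerics.R vpa.R
NULL

#' Stage coefficients for the NREM threshold circles
#'
#' The fixed ratios mapping the mean wakefulness CORE-vector magnitude to
#' the N1, N2 and N3 circle radii: 0.8778, 0.8077, 0.6544.
#'
#' @return named numeric vector (N1, N2, N3).
#' @export
stageCoefficients <- function() .STAGE_COEFFICIENTS

#' Mean CORE magnitude over a wakefulness baseline window
#'
#' Arithmetic mean of the per-sample vector magnitudes |R| over the given
#' time window of a trajectory.
#'
#' @param traj a [VpaTrajectory-class].
#' @param window length-2 numeric (start, end) in seconds, inclusive;
#'   NULL means the whole trajectory.
#' @return list with `rW` (mean magnitude, micromolar) and `n` (samples
#'   averaged).
#' @export
wakefulnessBaseline <- function(traj, window = NULL) {
  p <- trajectoryPoints(traj)
  if (is.null(window)) {
    sel <- rep(TRUE, nrow(p))
  } else {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    sel <- p$time_s >= window[1] & p$time_s <= window[2]
  }
  if (!any(sel)) stop("baseline window contains no samples")
  list(rW = mean(p$magnitude[sel]), n = sum(sel))
}

#' Threshold-circle radii from the wakefulness radius
#'
#' Scales the wakefulness radius by the fixed stage coefficients
#' (see [stageCoefficients()]) to obtain the N1/N2/N3 circle radii.
#'
#' @param rW mean wakefulness magnitude (micromolar), > 0.
#' @param n number of baseline samples behind `rW` (bookkeeping).
#' @param channel channel number (bookkeeping).
#' @return a [ThresholdSet-class].
#' @examples
#' sleepStageRadii(1.0)  # radii 0.8778, 0.8077, 0.6544
#' @export
sleepStageRadii <- function(rW, n = 0L, channel = 1L) {
  if (!is.numeric(rW) || length(rW) != 1L || !is.finite(rW) || rW <= 0) {
    stop("rW must be a single positive number")
  }
  k <- stageCoefficients()
  new("ThresholdSet", rW = rW, rN1 = unname(rW * k["N1"]),
      rN2 = unname(rW * k["N2"]), rN3 = unname(rW * k["N3"]),
      nBaseline = as.integer(n), channel = as.integer(channel))
}

#' Threshold radii as a named vector
#'
#' @param x a [ThresholdSet-class].
#' @return named numeric (W, N1, N2, N3), outermost first.
#' @export
thresholdRadii <- function(x) {
  stopifnot(is(x, "ThresholdSet"))
  c(W = x@rW, N1 = x@rN1, N2 = x@rN2, N3 = x@rN3)
}

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf(
    "ThresholdSet (channel %d, n = %d baseline samples)\n",
    object@channel, object@nBaseline))
  r <- thresholdRadii(object)
  cat(sprintf("  %s: %.6g uM\n", names(r), r), sep = "")
  invisible(object)
})

#' @describeIn calibrateThresholds calibrates every channel of a
#'   (preprocessed) hemodynamic recording over a wakefulness window.
#' @param baselineWindow length-2 numeric (start, end) seconds of the
#'   wakefulness segment; NULL uses the whole recording.
#' @param minSeconds minimum admissible baseline duration (default 30 s).
#' @export
setMethod("calibrateThresholds", "FnirsRecording",
          function(x, baselineWindow = NULL, minSeconds = 30, ...) {
  stopifnot(recordingKind(x) == "hemodynamic")
  dur <- if (is.null(baselineWindow)) {
    nrow(x) / samplingRate(x)
  } else {
    diff(baselineWindow)
  }
  if (dur < minSeconds) {
    stop(sprintf("baseline of %.3g s is shorter than the %.3g s minimum",
                 dur, minSeconds))
  }
  out <- lapply(seq_len(ncol(x)), function(ch) {
    b <- wakefulnessBaseline(buildTrajectory(x, ch), baselineWindow)
    sleepStageRadii(b$rW, b$n, ch)
  })
  names(out) <- colnames(x)
  out
})

#' @describeIn calibrateThresholds a list of baseline-trial recordings:
#'   per channel, the per-trial mean magnitudes are averaged (unweighted)
#'   before scaling to the stage radii.
#' @export
setMethod("calibrateThresholds", "list",
          function(x, baselineWindow = NULL, minSeconds = 30, ...) {
  stopifnot(length(x) >= 1L,
            all(vapply(x, is, logical(1), "FnirsRecording")))
  nch <- unique(vapply(x, ncol, integer(1)))
  if (length(nch) != 1L) stop("trials must share the channel layout")
  perTrial <- lapply(x, calibrateThresholds, baselineWindow = baselineWindow,
                     minSeconds = minSeconds)
  out <- lapply(seq_len(nch), function(ch) {
    rws <- vapply(perTrial, function(tr) tr[[ch]]@rW, numeric(1))
    ns <- vapply(perTrial, function(tr) tr[[ch]]@nBaseline, integer(1))
    sleepStageRadii(mean(rws), sum(ns), ch)
  })
  names(out) <- colnames(x[[1]])
  out
})
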
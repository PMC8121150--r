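#' @include AllClasses.R
NULL

#' Sampling rate of a recording or trajectory
#'
#' @param x a [FnirsRecording-class] or [VpaTrajectory-class] object.
#' @return Sampling rate in Hz (scalar numeric).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Kind of data a recording holds
#'
#' @param x a [FnirsRecording-class] object.
#' @return `"raw"` (two-wavelength intensities) or `"hemodynamic"`
#'   (HbO/HbR concentration changes).
#' @export
setGeneric("recordingKind", function(x) standardGeneric("recordingKind"))

#' Sample times
#'
#' @param x a [FnirsRecording-class] or [VpaTrajectory-class] object.
#' @return Numeric vector of sample times in seconds from recording start.
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' Map a hemodynamic recording channel onto the vector phase plane
#'
#' @param x a hemodynamic [FnirsRecording-class].
#' @param channel 1-based channel number.
#' @param ... unused.
#' @return A [VpaTrajectory-class] with one point per sample.
#' @export
setGeneric("buildTrajectory",
           function(x, channel, ...) standardGeneric("buildTrajectory"))

#' Calibrate sleep-stage threshold circles from a wakefulness baseline
#'
#' @param x a hemodynamic [FnirsRecording-class] (or a list of baseline-trial
#'   recordings, averaged per channel before scaling).
#' @param ... passed to methods; see [calibrateThresholds,FnirsRecording-method].
#' @return A list with one [ThresholdSet-class] per channel.
#' @export
setGeneric("calibrateThresholds",
           function(x, ...) standardGeneric("calibrateThresholds"))

#' Sliding-window drowsiness detection on a VPA trajectory
#'
#' @param x a [VpaTrajectory-class].
#' @param thresholds the channel's calibrated [ThresholdSet-class].
#' @param ... see the method for tuning parameters.
#' @return A data.frame of detection events (zero rows when none).
#' @export
setGeneric("detectDrowsiness",
           function(x, thresholds, ...) standardGeneric("detectDrowsiness"))

#' Windowed feature extraction from a VPA trajectory
#'
#' @param x a [VpaTrajectory-class].
#' @param windows data.frame with columns `start`, `end` (1-based sample
#'   indices, inclusive) and `label` (one of W, N1, N2, N3).
#' @param ... unused.
#' @return A [FeatureTable-class] with one row per window.
#' @export
setGeneric("extractFeatures",
           function(x, windows, ...) standardGeneric("extractFeatures"))
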
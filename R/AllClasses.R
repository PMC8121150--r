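#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData colData
NULL

.STAGES <- c("W", "N1", "N2", "N3")

## Fixed coefficients mapping the wakefulness mean radius to the NREM
## stage circle radii. Single source of truth; ordering asserted at load.
.STAGE_COEFFICIENTS <- c(N1 = 0.8778, N2 = 0.8077, N3 = 0.6544)

.onLoad <- function(libname, pkgname) {
  stopifnot(all(diff(.STAGE_COEFFICIENTS) < 0), all(.STAGE_COEFFICIENTS > 0),
            all(.STAGE_COEFFICIENTS < 1))
}

#' FnirsRecording: multichannel fNIRS time series
#'
#' Container for an fNIRS recording, built on
#' [SummarizedExperiment::SummarizedExperiment]: rows are time samples
#' (uniformly spaced), columns are channels, and assays hold either the two
#' raw wavelength intensity matrices (kind `"raw"`, assay names `"wl<nm>"`)
#' or the hemodynamic pair (kind `"hemodynamic"`, assays `"hbo"` and
#' `"hbr"`, micromolar). Metadata carries `sampling_rate` (Hz), `kind`,
#' `subject` and, for raw recordings, `wavelengths` (nm).
#'
#' Use [rawRecording()] / [hemodynamicRecording()] to construct one and
#' [samplingRate()], [recordingKind()], [sampleTimes()], [hbo()], [hbr()]
#' to access it.
#'
#' @aliases FnirsRecording
#' @export
setClass("FnirsRecording", contains = "SummarizedExperiment")

.validFnirsRecording <- function(object) {
  msg <- character()
  md <- metadata(object)
  fs <- md$sampling_rate
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L || !is.finite(fs) ||
      fs <= 0) {
    msg <- c(msg, "metadata$sampling_rate must be a single positive number")
  }
  kind <- md$kind
  if (is.null(kind) || !kind %in% c("raw", "hemodynamic")) {
    msg <- c(msg, "metadata$kind must be 'raw' or 'hemodynamic'")
  } else if (kind == "raw") {
    wl <- md$wavelengths
    if (length(wl) != 2L || !all(is.finite(wl)) || anyDuplicated(wl)) {
      msg <- c(msg, "raw recordings need exactly 2 distinct wavelengths")
    } else if (!identical(assayNames(object), paste0("wl", wl))) {
      msg <- c(msg, "raw assays must be named wl<nm> in wavelength order")
    }
  } else if (!identical(assayNames(object), c("hbo", "hbr"))) {
    msg <- c(msg, "hemodynamic assays must be exactly {hbo, hbr}")
  }
  for (nm in assayNames(object)) {
    if (!all(is.finite(assay(object, nm)))) {
      msg <- c(msg, sprintf("assay '%s' contains non-finite values", nm))
    }
  }
  t <- rowData(object)$time_s
  if (is.null(t)) {
    msg <- c(msg, "rowData must carry time_s")
  } else if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) msg <- c(msg, "time_s must be strictly increasing")
    if (is.numeric(fs) && length(fs) == 1L && is.finite(fs) && fs > 0 &&
        any(abs(dt - 1 / fs) > 1e-6 * (1 / fs))) {
      msg <- c(msg, "time_s spacing must equal 1/sampling_rate (rel. tol 1e-6)")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("FnirsRecording", .validFnirsRecording)

#' VpaTrajectory: a path on the vector phase plane
#'
#' Ordered per-sample points of one channel mapped onto the vector phase
#' plane: HbO/HbR coordinates, the pi/4-rotated HbT/COE coordinates, vector
#' magnitude |R| and angle in [0, 2*pi), and the octant phase 1-8 (NA where
#' the vector is zero and the phase is undefined).
#'
#' @slot points data.frame with columns time_s, hbo, hbr, hbt, coe,
#'   magnitude, angle, phase.
#' @slot channel 1-based channel number the trajectory came from.
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("VpaTrajectory",
         representation(points = "data.frame", channel = "integer",
                        samplingRate = "numeric"))

.validVpaTrajectory <- function(object) {
  msg <- character()
  p <- object@points
  need <- c("time_s", "hbo", "hbr", "hbt", "coe", "magnitude", "angle", "phase")
  if (!all(need %in% names(p))) {
    return(paste("points must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p) > 1L && any(diff(p$time_s) <= 0)) {
    msg <- c(msg, "time_s must be strictly increasing")
  }
  if (nrow(p)) {
    if (max(abs(p$hbt - (p$hbo + p$hbr))) > 1e-12 + 1e-12 * max(abs(p$hbt))) {
      msg <- c(msg, "hbt must equal hbo + hbr")
    }
    if (max(abs(p$coe - (p$hbr - p$hbo))) > 1e-12 + 1e-12 * max(abs(p$coe))) {
      msg <- c(msg, "coe must equal hbr - hbo")
    }
    bad <- !is.na(p$phase) & !(p$phase %in% 1:8)
    if (any(bad)) msg <- c(msg, "phase must be in 1..8 or NA")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(msg)) msg else TRUE
}
setValidity("VpaTrajectory", .validVpaTrajectory)

#' ThresholdSet: wakefulness and NREM threshold-circle radii
#'
#' Radii of the concentric threshold circles on the vector phase plane for
#' one channel: the wakefulness radius rW (mean baseline |R|) and the N1,
#' N2, N3 radii obtained by scaling rW with the fixed stage coefficients
#' 0.8778, 0.8077, 0.6544.
#'
#' @slot rW,rN1,rN2,rN3 circle radii in micromolar, rW > rN1 > rN2 > rN3 > 0.
#' @slot nBaseline number of baseline samples averaged to get rW.
#' @slot channel 1-based channel number.
#' @export
setClass("ThresholdSet",
         representation(rW = "numeric", rN1 = "numeric", rN2 = "numeric",
                        rN3 = "numeric", nBaseline = "integer",
                        channel = "integer"))

.validThresholdSet <- function(object) {
  msg <- character()
  r <- c(object@rW, object@rN1, object@rN2, object@rN3)
  if (length(r) != 4L || !all(is.finite(r))) {
    return("all four radii must be single finite numbers")
  }
  if (!(r[1] > r[2] && r[2] > r[3] && r[3] > r[4] && r[4] > 0)) {
    msg <- c(msg, "radii must satisfy rW > rN1 > rN2 > rN3 > 0")
  }
  expect <- object@rW * .STAGE_COEFFICIENTS
  if (max(abs(r[2:4] - expect) / expect) > 1e-12) {
    msg <- c(msg, "stage radii must equal the fixed coefficients times rW")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ThresholdSet", .validThresholdSet)

#' FeatureTable: windowed VPA + HbO features with stage labels
#'
#' One row per labeled analysis window: the six trajectory slopes
#' m(HbO), m(HbR), m(HbT), m(COE), m(angle), m(|R|) plus the HbO signal
#' mean M, peak P and sum of peaks SoP, together with the stage label,
#' channel and window id. After [minmaxRescale()] the `scaling` slot holds
#' the per-feature (min, max) used, so the same affine map can be reused
#' on held-out data.
#'
#' @slot features data.frame of the 9 numeric feature columns.
#' @slot label factor with levels W, N1, N2, N3.
#' @slot channel,window integer identifiers per row.
#' @slot scaled logical: has min-max rescaling been applied?
#' @slot scaling data.frame (feature, min, max, a, b); zero rows when raw.
#' @export
setClass("FeatureTable",
         representation(features = "data.frame", label = "factor",
                        channel = "integer", window = "integer",
                        scaled = "logical", scaling = "data.frame"))

.FEATURE_NAMES <- c("m_hbo", "m_hbr", "m_hbt", "m_coe", "m_angle", "m_mag",
                    "mean_hbo", "peak_hbo", "sop_hbo")

.validFeatureTable <- function(object) {
  msg <- character()
  if (!identical(names(object@features), .FEATURE_NAMES)) {
    msg <- c(msg, paste("features must have columns:",
                        paste(.FEATURE_NAMES, collapse = ", ")))
  }
  n <- nrow(object@features)
  if (length(object@label) != n || length(object@channel) != n ||
      length(object@window) != n) {
    msg <- c(msg, "label/channel/window must match the number of rows")
  }
  if (!identical(levels(object@label), .STAGES)) {
    msg <- c(msg, "label levels must be W, N1, N2, N3")
  }
  if (n && !all(vapply(object@features, function(x) all(is.finite(x)),
                       logical(1)))) {
    msg <- c(msg, "all feature values must be finite")
  }
  if (length(msg)) msg else TRUE
}
setValidity("FeatureTable", .validFeatureTable)

#' ClassificationReport: cross-validated multiclass performance
#'
#' Pooled out-of-fold results of a stratified k-fold run: the 4x4 confusion
#' matrix (rows true, columns predicted), the per-class one-vs-rest rates
#' TPR/FNR/TNR/FPR/PPV/FDR, overall accuracy, per-class one-vs-rest AUC,
#' and the classifier specification used.
#'
#' @slot confusion integer matrix of counts, rows = true classes.
#' @slot metrics data.frame of per-class rates (NA marks an undefined rate).
#' @slot accuracy overall fraction correct.
#' @slot auc named numeric per-class one-vs-rest AUC (NA when undefined).
#' @slot folds number of folds.
#' @slot classifier one of dt, da, svm, knn, ensemble.
#' @slot params classifier hyperparameters.
#' @slot wallTime elapsed seconds (informational only).
#' @export
setClass("ClassificationReport",
         representation(confusion = "matrix", metrics = "data.frame",
                        accuracy = "numeric", auc = "numeric",
                        folds = "integer", classifier = "character",
                        params = "list", wallTime = "numeric"))

.validClassificationReport <- function(object) {
  msg <- character()
  cm <- object@confusion
  if (any(cm < 0) || any(cm != round(cm))) {
    msg <- c(msg, "confusion counts must be nonnegative integers")
  }
  if (sum(cm) > 0 &&
      abs(object@accuracy - sum(diag(cm)) / sum(cm)) > 1e-12) {
    msg <- c(msg, "accuracy must equal trace(confusion)/sum(confusion)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ClassificationReport", .validClassificationReport)
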
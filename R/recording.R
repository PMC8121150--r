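#' @include AllClasses.R AllGenerics.R
NULL

.makeRecording <- function(assayList, samplingRate, kind, subject,
                           channelLabels = NULL, startTime = 0,
                           wavelengths = NULL) {
  m <- assayList[[1L]]
  if (is.null(dim(m))) {
    assayList <- lapply(assayList, function(x) matrix(x, ncol = 1L))
    m <- assayList[[1L]]
  }
  nT <- nrow(m)
  nC <- ncol(m)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nC))
  t <- startTime + (seq_len(nT) - 1L) / samplingRate
  cd <- DataFrame(channel = seq_len(nC), label = channelLabels,
                  row.names = channelLabels)
  assayList <- lapply(assayList, function(x) {
    dimnames(x) <- list(NULL, channelLabels)
    x
  })
  se <- SummarizedExperiment(assays = assayList,
                             rowData = DataFrame(time_s = t), colData = cd)
  md <- list(sampling_rate = samplingRate, kind = kind, subject = subject)
  if (kind == "raw") md$wavelengths <- wavelengths
  metadata(se) <- md
  new("FnirsRecording", se)
}

#' Construct a hemodynamic fNIRS recording
#'
#' @param hbo,hbr time x channel matrices of HbO / HbR concentration
#'   changes in micromolar (vectors are treated as single-channel).
#' @param samplingRate sampling rate in Hz.
#' @param subject subject identifier.
#' @param channelLabels optional channel names (default ch1..chN).
#' @param startTime time of the first sample in seconds.
#' @return A [FnirsRecording-class] of kind `"hemodynamic"`.
#' @examples
#' rec <- hemodynamicRecording(hbo = matrix(rnorm(20), 10),
#'                             hbr = matrix(rnorm(20), 10), samplingRate = 1.81)
#' dim(rec)
#' @export
hemodynamicRecording <- function(hbo, hbr, samplingRate, subject = "unknown",
                                 channelLabels = NULL, startTime = 0) {
  if (!identical(dim(as.matrix(hbo)), dim(as.matrix(hbr)))) {
    stop("hbo and hbr must have identical dimensions")
  }
  .makeRecording(list(hbo = as.matrix(hbo), hbr = as.matrix(hbr)),
                 samplingRate, "hemodynamic", subject, channelLabels,
                 startTime)
}

#' Construct a raw two-wavelength intensity recording
#'
#' @param intensity1,intensity2 time x channel matrices of detected light
#'   intensity at the first / second wavelength (arbitrary detector units,
#'   strictly positive).
#' @param wavelengths the two wavelengths in nm (default 760 and 830).
#' @inheritParams hemodynamicRecording
#' @return A [FnirsRecording-class] of kind `"raw"`.
#' @export
rawRecording <- function(intensity1, intensity2, samplingRate,
                         wavelengths = c(760, 830), subject = "unknown",
                         channelLabels = NULL, startTime = 0) {
  if (!identical(dim(as.matrix(intensity1)), dim(as.matrix(intensity2)))) {
    stop("the two intensity blocks must have identical dimensions")
  }
  a <- list(as.matrix(intensity1), as.matrix(intensity2))
  names(a) <- paste0("wl", wavelengths)
  .makeRecording(a, samplingRate, "raw", subject, channelLabels, startTime,
                 wavelengths = wavelengths)
}

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "FnirsRecording",
          function(x) metadata(x)$sampling_rate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "VpaTrajectory", function(x) x@samplingRate)

#' @rdname recordingKind
#' @export
setMethod("recordingKind", "FnirsRecording", function(x) metadata(x)$kind)

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "FnirsRecording", function(x) rowData(x)$time_s)

#' @rdname sampleTimes
#' @export
setMethod("sampleTimes", "VpaTrajectory", function(x) x@points$time_s)

#' Hemodynamic assay accessors
#'
#' @param x a hemodynamic [FnirsRecording-class].
#' @return time x channel matrix of HbO (resp. HbR) concentration changes.
#' @export
hbo <- function(x) {
  stopifnot(is(x, "FnirsRecording"), recordingKind(x) == "hemodynamic")
  assay(x, "hbo")
}

#' @rdname hbo
#' @export
hbr <- function(x) {
  stopifnot(is(x, "FnirsRecording"), recordingKind(x) == "hemodynamic")
  assay(x, "hbr")
}

#' Raw intensity accessor
#'
#' @param x a raw [FnirsRecording-class].
#' @param which 1 or 2 selecting the wavelength block.
#' @return time x channel intensity matrix.
#' @export
intensityBlock <- function(x, which = 1L) {
  stopifnot(is(x, "FnirsRecording"), recordingKind(x) == "raw",
            which %in% c(1L, 2L))
  assay(x, which)
}

setMethod("show", "FnirsRecording", function(object) {
  cat(sprintf("FnirsRecording (%s): %d samples x %d channels @ %.4g Hz\n",
              recordingKind(object), nrow(object), ncol(object),
              samplingRate(object)))
  cat(sprintf("  subject: %s; duration: %.1f s\n",
              metadata(object)$subject,
              nrow(object) / samplingRate(object)))
  if (recordingKind(object) == "raw") {
    cat(sprintf("  wavelengths: %s nm\n",
                paste(metadata(object)$wavelengths, collapse = ", ")))
  }
  invisible(object)
})
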
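#' @include AllClasses.R recording.R
NULL

#' Default specific extinction coefficients
#'
#' Loads the pinned extinction-coefficient table shipped with the package
#' (Prahl/Homer compilation for oxy- and deoxy-hemoglobin at 760 and
#' 830 nm, in micromolar^-1 cm^-1). Users supply their own table through
#' [mbllParameters()] when a different tabulation is preferred.
#'
#' @param path optional CSV with columns wavelength_nm, eps_hbo, eps_hbr.
#' @return data.frame with one row per wavelength.
#' @export
extinctionTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extinction_760_830.csv",
                        package = "fnirsvpa", mustWork = TRUE)
  }
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_hbo", "eps_hbr")
  if (!all(need %in% names(tab))) {
    stop("extinction table must have columns: ",
         paste(need, collapse = ", "))
  }
  tab
}

#' Parameters of the modified Beer-Lambert inversion
#'
#' Bundles the 2x2 extinction matrix E (rows = wavelengths, columns =
#' {HbO, HbR}, micromolar^-1 cm^-1), the source-detector distance l (cm)
#' and the per-wavelength differential path-length factor d. The scattering
#' loss term of the Beer-Lambert model is taken as time-constant, so it
#' cancels when optical density is differenced against the baseline; it is
#' never estimated here.
#'
#' @param wavelengths the two wavelengths in nm.
#' @param extinction optional 2x2 matrix overriding the shipped table;
#'   row i is wavelength i, columns are (HbO, HbR).
#' @param distance source-detector distance in cm (default 2.1).
#' @param dpf differential path-length factor, length 1 or 2 (default 6).
#' @param baselineSeconds length of the reference window at the start of
#'   the recording used to define baseline intensity (default 30 s; use
#'   300 s when a 5-minute baseline is available).
#' @return a list of class `MbllParameters`.
#' @export
mbllParameters <- function(wavelengths = c(760, 830), extinction = NULL,
                           distance = 2.1, dpf = 6,
                           baselineSeconds = 30) {
  if (is.null(extinction)) {
    tab <- extinctionTable()
    i <- match(wavelengths, tab$wavelength_nm)
    if (anyNA(i)) {
      stop("no shipped extinction coefficients for wavelengths ",
           paste(wavelengths[is.na(i)], collapse = ", "),
           " nm; supply `extinction` explicitly")
    }
    extinction <- as.matrix(tab[i, c("eps_hbo", "eps_hbr")])
    dimnames(extinction) <- list(paste0("wl", wavelengths), c("hbo", "hbr"))
  }
  extinction <- as.matrix(extinction)
  stopifnot(identical(dim(extinction), c(2L, 2L)), all(is.finite(extinction)))
  if (abs(det(extinction)) <= 1e-12) {
    stop("extinction matrix is singular (|det| <= 1e-12)")
  }
  stopifnot(length(distance) == 1L, distance > 0)
  dpf <- rep_len(dpf, 2L)
  stopifnot(all(dpf > 0))
  stopifnot(length(baselineSeconds) == 1L, baselineSeconds > 0)
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 distance = distance, dpf = dpf,
                 baselineSeconds = baselineSeconds),
            class = "MbllParameters")
}

#' Raw intensities to optical-density changes
#'
#' Computes the attenuation change dA(t; lambda) = ln(I_ref(lambda) /
#' I(t; lambda)) per channel and wavelength, where I_ref is the mean
#' detected intensity over the baseline window. On noiseless data the
#' baseline-window mean of dA is 0 by construction.
#'
#' @param rec a raw [FnirsRecording-class]; all intensities must be
#'   strictly positive.
#' @param baselineWindow integer range (1-based, inclusive) of baseline
#'   samples; defaults to the first 30 s of the recording.
#' @return list with `od` (list of two time x channel matrices, one per
#'   wavelength), `wavelengths` and the recording's sampling rate.
#' @export
intensityToOD <- function(rec, baselineWindow = NULL) {
  stopifnot(is(rec, "FnirsRecording"), recordingKind(rec) == "raw")
  if (is.null(baselineWindow)) {
    n <- max(1L, min(nrow(rec), floor(30 * samplingRate(rec))))
    baselineWindow <- c(1L, n)
  }
  baselineWindow <- as.integer(baselineWindow)
  stopifnot(length(baselineWindow) == 2L,
            baselineWindow[1] >= 1L, baselineWindow[2] >= baselineWindow[1],
            baselineWindow[2] <= nrow(rec))
  bw <- seq.int(baselineWindow[1], baselineWindow[2])
  od <- lapply(1:2, function(w) {
    I <- intensityBlock(rec, w)
    if (any(I <= 0)) {
      bad <- which(I <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-positive intensity at sample %d, channel %d, wavelength %d",
        bad[1], bad[2], w))
    }
    Iref <- colMeans(I[bw, , drop = FALSE])
    log(rep(Iref, each = nrow(I)) / I)
  })
  names(od) <- assayNames(rec)
  list(od = od, wavelengths = metadata(rec)$wavelengths,
       samplingRate = samplingRate(rec),
       subject = metadata(rec)$subject,
       channelLabels = colnames(rec),
       time = sampleTimes(rec))
}

#' Optical-density changes to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per sample:
#' (dHbO, dHbR)' = E^-1 (dA(l1)/(l d1), dA(l2)/(l d2))', with E the 2x2
#' extinction matrix, l the source-detector distance and d the DPF.
#' Output is in micromolar.
#'
#' @param od the result of [intensityToOD()].
#' @param params an `MbllParameters` object from [mbllParameters()].
#' @return a hemodynamic [FnirsRecording-class].
#' @export
odToConcentrations <- function(od, params = mbllParameters()) {
  stopifnot(inherits(params, "MbllParameters"), length(od$od) == 2L)
  Einv <- solve(params$extinction)
  scale <- 1 / (params$distance * params$dpf)
  a1 <- od$od[[1]] * scale[1]
  a2 <- od$od[[2]] * scale[2]
  hbo <- Einv[1, 1] * a1 + Einv[1, 2] * a2
  hbr <- Einv[2, 1] * a1 + Einv[2, 2] * a2
  hemodynamicRecording(hbo, hbr, od$samplingRate,
                       subject = od$subject %||% "unknown",
                       channelLabels = od$channelLabels,
                       startTime = if (length(od$time)) od$time[1] else 0)
}

#' Full raw-to-hemodynamic conversion
#'
#' Convenience wrapper: [intensityToOD()] followed by
#' [odToConcentrations()].
#'
#' @inheritParams intensityToOD
#' @inheritParams odToConcentrations
#' @return a hemodynamic [FnirsRecording-class].
#' @export
rawToHemodynamic <- function(rec, params = mbllParameters(),
                             baselineWindow = NULL) {
  if (is.null(baselineWindow)) {
    n <- max(1L, min(nrow(rec),
                     floor(params$baselineSeconds * samplingRate(rec))))
    baselineWindow <- c(1L, n)
  }
  odToConcentrations(intensityToOD(rec, baselineWindow), params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
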
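#' @include AllClasses.R AllGenerics.R vpa.R
NULL

#' Trajectory slope over a window
#'
#' Slope of a tracked quantity over an analysis window, defined as
#' (last value - first value) / N with N the number of samples in the
#' window. `perSecond = TRUE` divides by the window duration in seconds
#' instead (requires `samplingRate`).
#'
#' @param values ordered numeric window (length >= 2).
#' @param perSecond report the slope per second rather than per sample.
#' @param samplingRate Hz, needed when `perSecond`.
#' @return scalar slope.
#' @examples
#' trajectorySlope(0:8)  # (8 - 0) / 9
#' @export
trajectorySlope <- function(values, perSecond = FALSE, samplingRate = NULL) {
  n <- length(values)
  if (n < 2L) stop("slope needs a window of at least 2 samples")
  stopifnot(all(is.finite(values)))
  s <- (values[n] - values[1]) / n
  if (perSecond) {
    stopifnot(!is.null(samplingRate))
    s <- s * samplingRate
  }
  s
}

#' Windowed HbO statistics: mean, peak, sum of peaks
#'
#' M is the arithmetic mean of the window. Local maxima are interior
#' samples strictly greater than both neighbours (the first sample of a
#' plateau followed by a descent counts once); P is the largest local
#' maximum and SoP their sum. Windows with no interior local maximum
#' (monotone or constant) fall back to P = window maximum and SoP = 0,
#' with a message.
#'
#' @param values non-empty numeric window.
#' @return list with M, P, SoP and the local-maximum indices.
#' @examples
#' windowStats(c(0, 2, 1, 3, 0))  # M = 1.2, P = 3, SoP = 5
#' @export
windowStats <- function(values) {
  if (!length(values)) stop("window is empty")
  stopifnot(all(is.finite(values)))
  M <- mean(values)
  peaks <- localMaxima(values)
  if (length(peaks)) {
    list(M = M, P = max(values[peaks]), SoP = sum(values[peaks]),
         peaks = peaks)
  } else {
    message("window has no interior local maximum; P = max(window), SoP = 0")
    list(M = M, P = max(values), SoP = 0, peaks = integer())
  }
}

#' Interior local maxima of a vector
#'
#' Strict peaks: samples greater than both neighbours; for a plateau the
#' plateau's first sample counts, and only when the plateau is followed by
#' a descent (and preceded by an ascent).
#'
#' @param values numeric vector.
#' @return integer indices of local maxima (possibly empty).
#' @export
localMaxima <- function(values) {
  n <- length(values)
  if (n < 3L) return(integer())
  d <- diff(values)
  # direction of the next non-zero step at each position (plateau handling)
  after <- d
  for (i in rev(seq_len(n - 2L))) {
    if (after[i] == 0) after[i] <- after[i + 1L]
  }
  idx <- which(d[-length(d)] > 0 & after[-1] < 0) + 1L
  idx
}

#' @describeIn extractFeatures one [FeatureTable-class] row per labeled
#'   window: the six slopes of the HbO, HbR, HbT, COE, angle and |R|
#'   tracks plus (M, P, SoP) of HbO. Angle tracks are unwrapped within
#'   each window before the slope so a 2*pi wrap does not fake a jump.
#' @export
setMethod("extractFeatures", "VpaTrajectory", function(x, windows, ...) {
  p <- trajectoryPoints(x)
  need <- c("start", "end", "label")
  if (!is.data.frame(windows) || !all(need %in% names(windows))) {
    stop("windows must be a data.frame with columns start, end, label")
  }
  if (nrow(windows) == 0L) {
    return(new("FeatureTable",
               features = stats::setNames(
                 as.data.frame(matrix(numeric(), 0, 9)), .FEATURE_NAMES),
               label = factor(character(), levels = .STAGES),
               channel = integer(), window = integer(), scaled = FALSE,
               scaling = data.frame()))
  }
  if (anyNA(windows$label) || !all(windows$label %in% .STAGES)) {
    stop("every window needs a label among W, N1, N2, N3")
  }
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    i <- seq.int(windows$start[k], windows$end[k])
    if (length(i) < 2L) stop("windows need at least 2 samples")
    ang <- p$angle[i]
    if (anyNA(ang)) stop("window contains zero-vector samples (no angle)")
    ang <- unwrapAngles(ang)
    st <- suppressMessages(windowStats(p$hbo[i]))
    data.frame(m_hbo = trajectorySlope(p$hbo[i]),
               m_hbr = trajectorySlope(p$hbr[i]),
               m_hbt = trajectorySlope(p$hbt[i]),
               m_coe = trajectorySlope(p$coe[i]),
               m_angle = trajectorySlope(ang),
               m_mag = trajectorySlope(p$magnitude[i]),
               mean_hbo = st$M, peak_hbo = st$P, sop_hbo = st$SoP)
  })
  new("FeatureTable", features = do.call(rbind, rows),
      label = factor(windows$label, levels = .STAGES),
      channel = rep(x@channel, nrow(windows)),
      window = seq_len(nrow(windows)), scaled = FALSE,
      scaling = data.frame())
})

#' Unwrap a short angle track
#'
#' Adds multiples of 2*pi so successive differences lie in (-pi, pi].
#'
#' @param angles numeric vector of angles in radians.
#' @return unwrapped angles.
#' @export
unwrapAngles <- function(angles) {
  if (length(angles) < 2L) return(angles)
  d <- diff(angles)
  jump <- cumsum(c(0, -2 * pi * (d > pi) + 2 * pi * (d < -pi)))
  angles + jump
}

#' Combine feature tables
#'
#' Row-binds unscaled feature tables (e.g. one per channel).
#'
#' @param ... [FeatureTable-class] objects, or a single list of them.
#' @return one [FeatureTable-class].
#' @export
bindFeatureTables <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "FeatureTable")) {
    xs <- xs[[1]]
  }
  stopifnot(all(vapply(xs, is, logical(1), "FeatureTable")),
            !any(vapply(xs, function(x) x@scaled, logical(1))))
  new("FeatureTable",
      features = do.call(rbind, lapply(xs, function(x) x@features)),
      label = factor(unlist(lapply(xs, function(x) as.character(x@label))),
                     levels = .STAGES),
      channel = unlist(lapply(xs, function(x) x@channel)),
      window = unlist(lapply(xs, function(x) x@window)),
      scaled = FALSE, scaling = data.frame())
}

#' Feature matrix / labels accessors
#'
#' @param x a [FeatureTable-class].
#' @return `featureMatrix`: numeric matrix (rows = windows);
#'   `featureLabels`: factor of stage labels.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  as.matrix(x@features)
}

#' @rdname featureMatrix
#' @export
featureLabels <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@label
}

#' Min-max rescaling of a feature table
#'
#' Columnwise affine map of every feature to [a, b] (default [-1, 1]):
#' Y' = a + (Y - min)/(max - min) * (b - a). The (min, max) actually used
#' are stored in the returned table so the identical map can be applied to
#' held-out data via `scaling`.
#'
#' @param x a [FeatureTable-class].
#' @param a,b target range (default -1, 1).
#' @param scaling optional scaling data.frame from a previous call, to
#'   reuse a training-set map on new data.
#' @return the rescaled [FeatureTable-class] (`scaled = TRUE`).
#' @export
minmaxRescale <- function(x, a = -1, b = 1, scaling = NULL) {
  stopifnot(is(x, "FeatureTable"), a < b)
  f <- x@features
  if (is.null(scaling)) {
    mins <- vapply(f, min, numeric(1))
    maxs <- vapply(f, max, numeric(1))
    if (any(maxs <= mins)) {
      bad <- names(f)[maxs <= mins][1]
      stop(sprintf("feature '%s' is constant; min-max rescaling undefined",
                   bad))
    }
    scaling <- data.frame(feature = names(f), min = mins, max = maxs,
                          a = a, b = b, row.names = NULL)
  } else {
    stopifnot(identical(scaling$feature, names(f)))
    a <- scaling$a[1]
    b <- scaling$b[1]
  }
  for (j in seq_along(f)) {
    f[[j]] <- a + (f[[j]] - scaling$min[j]) /
      (scaling$max[j] - scaling$min[j]) * (b - a)
  }
  new("FeatureTable", features = f, label = x@label, channel = x@channel,
      window = x@window, scaled = TRUE, scaling = scaling)
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d windows x %d features (%s)\n",
              nrow(object@features), ncol(object@features),
              if (object@scaled) "rescaled" else "raw"))
  print(table(object@label))
  invisible(object)
})
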
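#' @include AllClasses.R AllGenerics.R recording.R
#' @importFrom graphics segments lines
NULL

#' Rotated vector-phase indices
#'
#' The vector phase plane takes HbO and HbR concentration changes as
#' orthogonal axes; rotating that frame by pi/4 counterclockwise yields the
#' total-hemoglobin axis HbT = HbO + HbR and the cerebral-oxygen-exchange
#' axis COE = HbR - HbO.
#'
#' @param hbo,hbr numeric vectors (micromolar), recycled to common length.
#' @return data.frame with columns `hbt` and `coe`.
#' @examples
#' deriveIndices(1, 0)   # hbt = 1, coe = -1
#' @export
deriveIndices <- function(hbo, hbr) {
  stopifnot(all(is.finite(hbo)), all(is.finite(hbr)))
  data.frame(hbt = hbo + hbr, coe = hbr - hbo)
}

#' Magnitude of the CORE vector
#'
#' |R| = sqrt(hbo^2 + hbr^2); equivalently sqrt((hbt^2 + coe^2)/2) in the
#' rotated frame (the pi/4 rotation used here carries a sqrt(2) scale).
#'
#' @param hbo,hbr numeric vectors (micromolar).
#' @return numeric vector of magnitudes.
#' @export
vectorMagnitude <- function(hbo, hbr) {
  stopifnot(all(is.finite(hbo)), all(is.finite(hbr)))
  sqrt(hbo^2 + hbr^2)
}

#' Angle of the CORE vector
#'
#' Quadrant-aware angle of (hbo, hbr), measured counterclockwise from the
#' +HbO axis and mapped to [0, 2*pi). It satisfies the rotated-frame
#' identity angle(hbo, hbr) = angle(hbt, coe) + pi/4 (mod 2*pi).
#'
#' @param hbo,hbr numeric vectors (micromolar); a zero vector has no angle.
#' @return numeric vector of angles in radians, in [0, 2*pi).
#' @export
vectorAngle <- function(hbo, hbr) {
  stopifnot(all(is.finite(hbo)), all(is.finite(hbr)))
  if (any(hbo == 0 & hbr == 0)) {
    stop("angle undefined for the zero vector")
  }
  a <- atan2(hbr, hbo)
  ifelse(a < 0, a + 2 * pi, a)
}

#' Octant phase of a point on the vector phase plane
#'
#' The plane is split into eight pi/4 sectors ("phases") by the HbO/HbR
#' axes and the rotated HbT/COE axes; phase k covers angles in
#' [(k-1)*pi/4, k*pi/4) (left-closed, right-open). Each phase carries a
#' characteristic sign pattern of the four indices (e.g. phase 7:
#' HbO > 0, HbR < 0, HbT < 0, COE < 0, HbT > COE).
#'
#' @param hbo,hbr numeric vectors; a zero vector has an undefined phase.
#' @param naZero if TRUE, zero vectors yield NA instead of an error
#'   (used when mapping whole trajectories).
#' @return integer vector of phases in 1..8 (NA only when `naZero`).
#' @examples
#' classifyPhase(2, 1)    # HbO > HbR > 0: phase 1 (initial-dip sector)
#' classifyPhase(1, -2)   # fourth quadrant, HbT > COE: phase 7
#' @export
classifyPhase <- function(hbo, hbr, naZero = FALSE) {
  stopifnot(all(is.finite(hbo)), all(is.finite(hbr)))
  zero <- hbo == 0 & hbr == 0
  if (any(zero) && !naZero) stop("phase undefined for the zero vector")
  ang <- atan2(hbr, hbo)
  ang <- ifelse(ang < 0, ang + 2 * pi, ang)
  ph <- as.integer(floor(ang / (pi / 4))) + 1L
  ph[ph > 8L] <- 8L  # guards angle == 2*pi from rounding
  ph[zero] <- NA_integer_
  ph
}

#' @describeIn buildTrajectory one point per sample of the chosen channel;
#'   zero-vector samples get NA angle and phase rather than failing.
#' @export
setMethod("buildTrajectory", "FnirsRecording", function(x, channel, ...) {
  stopifnot(recordingKind(x) == "hemodynamic")
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) || channel < 1L ||
      channel > ncol(x)) {
    stop(sprintf("unknown channel %s (recording has %d channels)",
                 paste(channel, collapse = ","), ncol(x)))
  }
  o <- hbo(x)[, channel]
  r <- hbr(x)[, channel]
  idx <- deriveIndices(o, r)
  zero <- o == 0 & r == 0
  ang <- rep(NA_real_, length(o))
  if (any(!zero)) ang[!zero] <- vectorAngle(o[!zero], r[!zero])
  new("VpaTrajectory",
      points = data.frame(time_s = sampleTimes(x), hbo = o, hbr = r,
                          hbt = idx$hbt, coe = idx$coe,
                          magnitude = vectorMagnitude(o, r), angle = ang,
                          phase = classifyPhase(o, r, naZero = TRUE)),
      channel = channel, samplingRate = samplingRate(x))
})

#' Points of a VPA trajectory as a data.frame
#'
#' @param x a [VpaTrajectory-class].
#' @return data.frame with columns time_s, hbo, hbr, hbt, coe, magnitude,
#'   angle, phase.
#' @export
trajectoryPoints <- function(x) {
  stopifnot(is(x, "VpaTrajectory"))
  x@points
}

#' Channel of a VPA trajectory
#' @param x a [VpaTrajectory-class].
#' @return integer channel number.
#' @export
trajectoryChannel <- function(x) {
  stopifnot(is(x, "VpaTrajectory"))
  x@channel
}

setMethod("length", "VpaTrajectory", function(x) nrow(x@points))

setMethod("show", "VpaTrajectory", function(object) {
  p <- object@points
  cat(sprintf("VpaTrajectory: channel %d, %d points @ %.4g Hz\n",
              object@channel, nrow(p), object@samplingRate))
  if (nrow(p)) {
    tab <- table(factor(p$phase, levels = 1:8))
    cat("  phase occupancy:",
        paste(sprintf("%d:%d", 1:8, as.integer(tab)), collapse = " "), "\n")
  }
  invisible(object)
})

#' Draw a vector phase diagram with a trajectory and threshold circles
#'
#' Basic rendering helper: octant spokes, the trajectory path, and (when a
#' [ThresholdSet-class] is given) the four stage circles.
#'
#' @param traj a [VpaTrajectory-class].
#' @param thresholds optional [ThresholdSet-class].
#' @param ... passed to [plot()].
#' @return invisibly, `traj`.
#' @export
plotPhaseDiagram <- function(traj, thresholds = NULL, ...) {
  p <- trajectoryPoints(traj)
  lim <- max(abs(c(p$hbo, p$hbr)), if (!is.null(thresholds)) thresholds@rW)
  lim <- lim * 1.1
  plot(p$hbo, p$hbr, type = "l", xlim = c(-lim, lim), ylim = c(-lim, lim),
       xlab = expression(Delta * HbO ~ (mu * M)),
       ylab = expression(Delta * HbR ~ (mu * M)), asp = 1, ...)
  for (k in 0:7) {
    a <- k * pi / 4
    segments(0, 0, lim * cos(a), lim * sin(a), col = "grey80")
  }
  if (!is.null(thresholds)) {
    th <- seq(0, 2 * pi, length.out = 181)
    for (r in c(thresholds@rW, thresholds@rN1, thresholds@rN2,
                thresholds@rN3)) {
      lines(r * cos(th), r * sin(th), lty = 2, col = "grey40")
    }
  }
  invisible(traj)
}
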
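#' @include AllClasses.R recording.R vpa.R thresholds.R
#' @importFrom stats rnorm runif
NULL

.STAGE_SECTORS <- list(W = c(pi / 2, pi),          # octant phases 3-4
                       N1 = c(3 * pi / 2, 2 * pi), # octant phases 7-8
                       N2 = c(3 * pi / 2, 2 * pi),
                       N3 = c(3 * pi / 2, 2 * pi))

#' Configuration of the synthetic fNIRS generator
#'
#' Describes the stage-dependent CORE geometry the generator emulates:
#' wakefulness samples concentrate in octant phases 3-4 and NREM samples
#' in phases 7-8, with mean vector magnitudes equal to the wakefulness
#' base radius scaled by the fixed stage coefficients (1, 0.8778, 0.8077,
#' 0.6544). Physiological interference is superposed as pure seeded-phase
#' sinusoids in the respiration, cardiac and very-low-frequency drift
#' bands, plus white noise.
#'
#' @param seed integer RNG seed.
#' @param fs sampling rate in Hz (default 1.81).
#' @param nChannels number of channels (default 8).
#' @param baseRadius wakefulness mean magnitude r_w* in micromolar
#'   (default 1; the pipeline is scale-covariant).
#' @param stagePlan data.frame(stage, duration_s); stages among W, N1,
#'   N2, N3. Default: one 300 s (~543-sample) block per stage.
#' @param radialNoiseSd sd of the radial perturbation, micromolar
#'   (default 0.05 * baseRadius).
#' @param whiteNoiseSd sd of additive white noise on each coordinate
#'   (default 0.01).
#' @param physio list of (freq_hz, amplitude) pairs for respiration,
#'   cardiac and drift sinusoids; amplitudes in micromolar.
#' @param angleModel `"uniform"` draws angles uniformly within the stage
#'   sector; `"vonmises"` concentrates them at the sector centre.
#' @param kappa von Mises concentration (only for `angleModel =
#'   "vonmises"`).
#' @return list of class `SynthConfig`.
#' @export
synthConfig <- function(seed = 1L, fs = 1.81, nChannels = 8L,
                        baseRadius = 1.0,
                        stagePlan = data.frame(
                          stage = c("W", "N1", "N2", "N3"),
                          duration_s = 300),
                        radialNoiseSd = 0.05 * baseRadius,
                        whiteNoiseSd = 0.01,
                        physio = list(respiration = c(0.35, 0.02),
                                      cardiac = c(1.1, 0.02),
                                      drift = c(0.005, 0.05)),
                        angleModel = c("uniform", "vonmises"),
                        kappa = 4) {
  stopifnot(fs > 0, nChannels >= 1L, baseRadius > 0,
            all(stagePlan$duration_s > 0),
            all(stagePlan$stage %in% .STAGES),
            radialNoiseSd >= 0, whiteNoiseSd >= 0,
            all(vapply(physio, function(p) p[2] >= 0, logical(1))))
  structure(list(seed = as.integer(seed), fs = fs,
                 nChannels = as.integer(nChannels),
                 baseRadius = baseRadius, stagePlan = stagePlan,
                 radialNoiseSd = radialNoiseSd,
                 whiteNoiseSd = whiteNoiseSd, physio = physio,
                 angleModel = match.arg(angleModel), kappa = kappa),
            class = "SynthConfig")
}

#' Stage radii implied by a generator configuration
#'
#' @param cfg a `SynthConfig`.
#' @return named numeric (W, N1, N2, N3) in micromolar.
#' @export
synthStageRadii <- function(cfg) {
  c(W = cfg$baseRadius, cfg$baseRadius * stageCoefficients())
}

.withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.drawAngles <- function(cfg, stage, n) {
  sector <- .STAGE_SECTORS[[stage]]
  if (cfg$angleModel == "uniform") {
    runif(n, sector[1], sector[2])
  } else {
    mu <- mean(sector)
    # wrapped von Mises draws folded back into the sector
    a <- mu + atan2(sin(stats::rnorm(n, 0, 1 / sqrt(cfg$kappa))),
                    cos(stats::rnorm(n, 0, 1 / sqrt(cfg$kappa))))
    pmin(pmax(a, sector[1] + 1e-9), sector[2] - 1e-9)
  }
}

.drawRadii <- function(radius, sd, n) {
  r <- rnorm(n, radius, sd)
  tries <- 0L
  while (any(r <= 0)) {
    bad <- r <= 0
    r[bad] <- rnorm(sum(bad), radius, sd)
    tries <- tries + sum(bad)
    if (tries > 1e6) stop("radius rejection sampling did not converge")
  }
  if (tries > 0L) {
    message(sprintf("resampled %d non-positive radius draw(s)", tries))
  }
  r
}

.physioSignal <- function(cfg, n) {
  t <- (seq_len(n) - 1L) / cfg$fs
  sig <- numeric(n)
  for (p in cfg$physio) {
    sig <- sig + p[2] * sin(2 * pi * p[1] * t + runif(1, 0, 2 * pi))
  }
  sig
}

.assemble <- function(cfg, angles, radii) {
  n <- length(angles)
  hbo <- radii * cos(angles) + .physioSignal(cfg, n) +
    rnorm(n, 0, cfg$whiteNoiseSd)
  hbr <- radii * sin(angles) + .physioSignal(cfg, n) +
    rnorm(n, 0, cfg$whiteNoiseSd)
  cbind(hbo, hbr)
}

#' Generate a stage-labeled synthetic recording
#'
#' Per sample, an angle is drawn from the stage's octant sector (W: phases
#' 3-4; N1/N2/N3: phases 7-8) and a radius from a Gaussian centred on the
#' stage radius (negative draws are rejected and resampled, with a
#' message); the polar point is mapped back to (HbO, HbR) and the
#' physiological sinusoids and white noise are superposed. Fully
#' deterministic for a given config.
#'
#' @param cfg a `SynthConfig` from [synthConfig()].
#' @return list with `recording` (hemodynamic [FnirsRecording-class]) and
#'   `labels` (per-sample stage factor).
#' @export
generateStageRecording <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  radii <- synthStageRadii(cfg)
  nPer <- pmax(1L, round(cfg$stagePlan$duration_s * cfg$fs))
  labels <- factor(rep(cfg$stagePlan$stage, nPer), levels = .STAGES)
  n <- length(labels)
  .withSeed(cfg$seed, {
    hbo <- matrix(0, n, cfg$nChannels)
    hbr <- matrix(0, n, cfg$nChannels)
    for (ch in seq_len(cfg$nChannels)) {
      ang <- numeric(n)
      rad <- numeric(n)
      pos <- 1L
      for (k in seq_len(nrow(cfg$stagePlan))) {
        i <- seq.int(pos, pos + nPer[k] - 1L)
        st <- cfg$stagePlan$stage[k]
        ang[i] <- .drawAngles(cfg, st, nPer[k])
        rad[i] <- .drawRadii(radii[[st]], cfg$radialNoiseSd, nPer[k])
        pos <- pos + nPer[k]
      }
      xy <- .assemble(cfg, ang, rad)
      hbo[, ch] <- xy[, 1]
      hbr[, ch] <- xy[, 2]
    }
    list(recording = hemodynamicRecording(hbo, hbr, cfg$fs,
                                          subject = "synthetic"),
         labels = labels)
  })
}

#' Generate a wake-to-drowsiness transition recording
#'
#' The noiseless base path holds the wakefulness sector (angle 3*pi/4,
#' radius 0.9 r_w*) for `wakeSeconds`, then drifts the angle linearly into
#' the middle of the phase-7/8 sector (7*pi/4) while the radius ramps
#' linearly from 0.9 to 1.3 r_w* over `transitionSeconds`, then holds the
#' drowsy state for `drowsySeconds`. Noise is superposed as in
#' [generateStageRecording()]. The ground-truth onset is found by brute
#' force: the sliding-window detection predicate (window means plus the
#' instantaneous phase-7/8 and magnitude conditions against the ideal
#' thresholds with rW = r_w*) is evaluated sample by sample on the
#' noiseless path.
#'
#' @param cfg a `SynthConfig`.
#' @param wakeSeconds,transitionSeconds,drowsySeconds segment durations.
#' @param nTransitions number of wake-transition-drowsy blocks.
#' @param windowSeconds detection window used for the ground truth.
#' @return list with `recording`, `thresholds` (ideal [ThresholdSet-class]
#'   per channel), `truthOnsets` (1-based sample indices of the noiseless
#'   predicate's maximal-run onsets), `truthTimes` (seconds) and `labels`.
#' @export
generateTransitionRecording <- function(cfg, wakeSeconds = 60,
                                        transitionSeconds = 30,
                                        drowsySeconds = 30,
                                        nTransitions = 1L,
                                        windowSeconds = 5) {
  stopifnot(inherits(cfg, "SynthConfig"), nTransitions >= 1L)
  fs <- cfg$fs
  rw <- cfg$baseRadius
  nW <- max(1L, round(wakeSeconds * fs))
  nT <- max(2L, round(transitionSeconds * fs))
  nD <- max(1L, round(drowsySeconds * fs))
  blockAng <- c(rep(3 * pi / 4, nW),
                seq(3 * pi / 4, 7 * pi / 4, length.out = nT),
                rep(7 * pi / 4, nD))
  blockRad <- c(rep(0.9 * rw, nW),
                seq(0.9 * rw, 1.3 * rw, length.out = nT),
                rep(1.3 * rw, nD))
  blockLab <- rep(c("W", "TRANSITION", "N1"), c(nW, nT, nD))
  ang0 <- rep(blockAng, nTransitions)
  rad0 <- rep(blockRad, nTransitions)
  labels <- factor(rep(blockLab, nTransitions),
                   levels = c(.STAGES, "TRANSITION"))
  n <- length(ang0)

  # brute-force ground truth on the noiseless path
  w <- ceiling(windowSeconds * fs)
  active <- logical(n)
  for (i in seq.int(w, n)) {
    win <- seq.int(i - w + 1L, i)
    ma <- mean(ang0[win])
    mm <- mean(rad0[win])
    ph <- floor((ang0[i] %% (2 * pi)) / (pi / 4)) + 1
    active[i] <- ma > 3 * pi / 4 && ma < 2 * pi && mm > rw &&
      ph %in% c(7, 8) && rad0[i] > rw
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  truth <- (ends - r$lengths + 1L)[r$values]

  rec <- .withSeed(cfg$seed + 1L, {
    hbo <- matrix(0, n, cfg$nChannels)
    hbr <- matrix(0, n, cfg$nChannels)
    for (ch in seq_len(cfg$nChannels)) {
      rad <- rad0 + rnorm(n, 0, cfg$radialNoiseSd)
      rad[rad <= 0] <- 1e-6
      xy <- .assemble(cfg, ang0, rad)
      hbo[, ch] <- xy[, 1]
      hbr[, ch] <- xy[, 2]
    }
    hemodynamicRecording(hbo, hbr, fs, subject = "synthetic")
  })
  thr <- lapply(seq_len(cfg$nChannels), function(ch) {
    sleepStageRadii(rw, n = 0L, channel = ch)
  })
  list(recording = rec, thresholds = thr, truthOnsets = truth,
       truthTimes = (truth - 1L) / fs, labels = labels)
}

#' Forward-model raw intensities from a hemodynamic recording
#'
#' Maps (HbO, HbR) through the Beer-Lambert forward model to attenuation
#' changes dA(lambda) = (eps_HbO(lambda) HbO + eps_HbR(lambda) HbR) * l *
#' d(lambda) and emits intensities I(t) = I_ref * exp(-dA). A baseline pad
#' of exactly zero hemodynamics (length `params$baselineSeconds`) is
#' prepended so the downstream baseline-referenced inversion recovers the
#' inputs exactly.
#'
#' @param rec a hemodynamic [FnirsRecording-class] (e.g. from
#'   [generateStageRecording()]).
#' @param params [mbllParameters()].
#' @param iRef reference detected intensity (arbitrary detector units).
#' @return a raw [FnirsRecording-class]; its first
#'   `baselineSeconds * fs` samples are the zero-hemodynamics pad.
#' @export
generateRawIntensity <- function(rec, params = mbllParameters(),
                                 iRef = 1000) {
  stopifnot(is(rec, "FnirsRecording"), recordingKind(rec) == "hemodynamic")
  fs <- samplingRate(rec)
  nPad <- max(1L, floor(params$baselineSeconds * fs))
  pad <- matrix(0, nPad, ncol(rec))
  o <- rbind(pad, hbo(rec))
  r <- rbind(pad, hbr(rec))
  E <- params$extinction
  ld <- params$distance * params$dpf
  I1 <- iRef * exp(-(E[1, 1] * o + E[1, 2] * r) * ld[1])
  I2 <- iRef * exp(-(E[2, 1] * o + E[2, 2] * r) * ld[2])
  rawRecording(I1, I2, fs, wavelengths = params$wavelengths,
               subject = metadata(rec)$subject,
               channelLabels = colnames(rec))
}
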
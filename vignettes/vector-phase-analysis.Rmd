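---
title: "Vector phase analysis of fNIRS hemodynamics: model, thresholds, detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector phase analysis of fNIRS hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsvpa)
```

## The measurement model

Continuous-wave fNIRS instruments record detected light intensity
$I(t;\lambda)$ at two near-infrared wavelengths (here 760 and 830 nm) per
optode channel. Attenuation changes relative to a baseline window,

$$\Delta A(t;\lambda) = \ln\frac{\bar I_{\mathrm{ref}}(\lambda)}{I(t;\lambda)},$$

are inverted through the modified Beer–Lambert law to micromolar
concentration changes of oxy- and deoxy-hemoglobin:

$$\begin{pmatrix}\Delta HbO\\ \Delta HbR\end{pmatrix}
 = E^{-1}\begin{pmatrix}\Delta A(\lambda_1)/(l\,d_1)\\
                        \Delta A(\lambda_2)/(l\,d_2)\end{pmatrix},$$

with $E$ the $2\times 2$ specific-extinction matrix, $l$ the
source–detector distance and $d_\lambda$ the differential path-length
factor. The scattering-loss term of the Beer–Lambert model is assumed
time-constant and cancels in the baseline differencing; it is documented,
never estimated. `intensityToOD()` and `odToConcentrations()` implement
the two steps; `rawToHemodynamic()` chains them.

Defaults, all overridable through `mbllParameters()`:

| parameter | default | unit | note |
|---|---|---|---|
| extinction matrix | Prahl/Homer values for 760/830 nm | µM⁻¹·cm⁻¹ | pinned in `inst/extdata/extinction_760_830.csv` |
| source–detector distance $l$ | 2.1 | cm | typical close-spacing montage |
| DPF $d_\lambda$ | 6.0 | – | common adult-forehead convention |
| baseline window | first 30 s | s | use 300 s when a 5-min rest baseline exists |

No extinction tabulation or DPF is universal; absolute µM magnitudes are
therefore convention-dependent. Everything downstream is scale-covariant
up to threshold calibration, which is performed per subject anyway.

## The vector phase plane

A sample is the vector $R = (\Delta HbO, \Delta HbR)$. Rotating the frame
by $\pi/4$ counterclockwise produces the total-hemoglobin and
cerebral-oxygen-exchange axes

$$\Delta HbT = \Delta HbO + \Delta HbR,\qquad
  \Delta COE = \Delta HbR - \Delta HbO,$$

so that

$$|R| = \sqrt{\Delta HbO^2 + \Delta HbR^2}
      = \sqrt{(\Delta HbT^2 + \Delta COE^2)/2},\qquad
  \angle R = \operatorname{atan2}(\Delta HbR, \Delta HbO)
           = \angle(\Delta HbT, \Delta COE) + \pi/4 .$$

The four axes cut the plane into eight $\pi/4$ octants ("phases"), each
with a characteristic sign pattern of the four indices. `classifyPhase()`
uses the angle rule $k = \lfloor \angle R / (\pi/4)\rfloor + 1$; the test
suite checks it against an independent classifier built from the sign
patterns alone.

Numerical conventions (deliberate, and load-bearing for reproducibility):

* angles live in $[0, 2\pi)$, measured counterclockwise from the
  $+\Delta HbO$ axis, so phases 1–8 are consecutive sectors;
* sector membership is left-closed, right-open: a point exactly on a
  boundary belongs to the sector it opens. Boundaries are measure-zero,
  so this only matters for constructed inputs;
* the zero vector has no angle; trajectory building marks such samples
  with an `NA` phase instead of failing, and scalar `vectorAngle()` /
  `classifyPhase()` raise an error. Honesty beats a silent convention;
* in octant 8 the sign pattern ($\Delta HbT > 0$, $\Delta COE < 0$)
  makes a signed comparison of the two rotated indices vacuous; where a
  within-octant comparison is wanted it is the magnitude comparison
  $|\Delta HbT| < |\Delta COE|$, which octant 8 always satisfies.

## Sleep-stage threshold circles

The wakefulness radius is the arithmetic mean $\overline{|R_W|}$ of the
per-sample magnitudes over a wakefulness baseline (5 min when available;
`calibrateThresholds()` refuses anything under 30 s). Multiple baseline
trials are combined as an unweighted mean of per-trial means — the
combination rule is not dictated by anything stronger than symmetry. The
NREM circle radii follow from the fixed coefficients

$$\big(\overline{|R_{N1}|}, \overline{|R_{N2}|}, \overline{|R_{N3}|}\big)
  = (0.8778,\; 0.8077,\; 0.6544)\;\overline{|R_W|},$$

which this package treats as given constants (they derive from prior
sleep-fNIRS findings, not from any fit performed here); their ordering is
asserted at load time and they live in one source-of-truth table,
`stageCoefficients()`.

## Drowsiness detection

Wakeful attention concentrates trajectories in phases 3–4 (second
quadrant: oxygen consumption, rising $\Delta COE$); drowsiness moves them
into phases 7–8 (fourth quadrant: rising $\Delta HbO$, falling
$\Delta COE$). Over a sliding window of $\lceil 5\,\mathrm{s}\cdot
f_s\rceil$ samples (10 samples at 1.81 Hz), advanced one sample at a
time, `detectDrowsiness()` requires

1. **angle criterion, evaluated first**: the window mean angle lies
   strictly in $(3\pi/4,\; 2\pi)$;
2. **magnitude criterion**: the window mean magnitude strictly exceeds
   $\overline{|R_W|}$;
3. **crossing localization**: the instantaneous sample is in phase 7 or
   8 with $|R| > \overline{|R_W|}$.

The printed lower bound $3\pi/4$ admits mean angles far outside the
fourth quadrant; the instantaneous phase-7/8 condition is what localizes
the crossing and reconciles the permissive bound with the
fourth-quadrant crossing rule. Both the bound and the window width are
configurable.

The angle mean is arithmetic, exactly as the criterion is written, with
angles taken in $[0,2\pi)$: the drowsiness sector does not straddle the
wrap, so the arithmetic mean is safe there; a circular (resultant
vector) mean is available via `circular = TRUE` for windows that do.
Maximal runs of consecutive active samples are reported as one event
each, by onset; no merging across gaps is performed. The
`crossed_circle` column is a stage-grading extension: it names the
innermost circle whose radius the onset window mean also exceeds — under
the magnitude criterion as printed (comparison against the W radius
only) that is always N3 once an event exists, so the column only becomes
informative if the magnitude criterion is re-targeted at an inner circle
via `checkCriteria(..., circle =)`.

`activeChannels()` ranks channels by event count (ties: earliest onset),
reproducing the "most active channel" analysis.

## Filtering

Physiological interference is removed by a unit-area Gaussian kernel
(default $\sigma$ = 1.5 samples, truncated at $\pm 4\sigma$,
reflect-padded) followed by zero-phase Butterworth band rejection:
order-4 band-stops at 0.3–0.4 Hz (respiration) and 1–1.2 Hz (cardiac),
and the sub-0.01 Hz band as an order-2 high-pass at 0.01 Hz. At
$f_s = 1.81$ Hz the cardiac band lies above Nyquist (0.905 Hz) and is
**skipped with a warning** rather than silently aliased; bands straddling
Nyquist are clipped to 99% of Nyquist, also with a warning. The slow band
is labeled for Mayer-wave removal in the source conventions this package
follows, although Mayer waves are conventionally ~0.1 Hz; the cutoff is
implemented exactly as specified (0.01 Hz) and exposed in the filter
configuration.

One practical consequence, visible with the synthetic generator: a
high-pass at 0.01 Hz removes any component that is constant on the
100-second scale — including the deliberately block-stationary stage
geometry of `generateStageRecording()`, whose 5-minute constant-radius
stages are sub-0.01 Hz content. Real transitions ride on faster
dynamics, so the pipeline keeps the filter-then-calibrate order for
recorded data; the geometric property checks in the test suite calibrate
on the generator's hemodynamics directly, which is also the condition
those properties state.

## Features and classification

Per labeled 5-s window, nine features: the trajectory slopes
$m(X) = (X_N - X_1)/N$ of the six tracks $\Delta HbO$, $\Delta HbR$,
$\Delta HbT$, $\Delta COE$, $\angle R$, $|R|$ — the divisor is the
window length in samples $N$, exactly as the defining formula divides by
the length of the sample vector (a per-second variant exists via
`perSecond = TRUE`) — plus the $\Delta HbO$ statistics mean $M$, peak
$P$ (largest strict interior local maximum) and sum of peaks $SoP$.
Angle tracks are unwrapped within a window before the slope so a
$2\pi$ wrap cannot fake a jump. Degenerate windows with no interior
local maximum (monotone or constant) fall back to $P$ = window maximum
and $SoP = 0$, with a message: the defining procedure never covers this
case, and the fallback keeps $P$ finite without inventing peaks.
Plateaus count once, at their first sample, and only when genuinely
ascended-to and descended-from.

Features are min–max rescaled columnwise to $[-1, 1]$ over the pooled
training table, the per-column $(\min,\max)$ being stored so the same
affine map can be applied to held-out data. Five classifier families are
wired with field-conventional defaults: decision tree; linear
discriminant analysis; RBF-kernel SVM with kernel scale 0.5 — the "fine
Gaussian" preset's $c = 0.5$ is read as the kernel scale
($\gamma = 1/(2 \cdot 0.5^2) = 2$), with box constraint 1, both
configurable, and one-vs-one decomposition; 1-nearest-neighbour; and
bagged decision trees (100 learners) as the ensemble. Cross-validation
is stratified 10-fold with a mandatory seed; out-of-fold predictions are
pooled into one confusion matrix from which the one-vs-rest rates TPR,
FNR, TNR, FPR, PPV, FDR are computed (complement identities hold to
1e-12; zero-denominator rates are `NA`, never 0). One-vs-rest AUC uses
the rank statistic on pooled out-of-fold scores.
`pairwiseFeatureScreen()` reproduces the 36-pair two-feature accuracy
table; `compareClassifiers()` runs paired t-tests of a reference
classifier against the rest at $\alpha = 0.05$, with degenerate-variance
pairings handled explicitly ($t = 0$, $p = 1$ when identical).

## The synthetic generator

The study dataset behind this method is not public, so
`generateStageRecording()` produces recordings with the geometry the
method assumes: per sample an angle drawn uniformly in the stage sector
(wakefulness: $(\pi/2, \pi)$, i.e. phases 3–4; NREM: $(3\pi/2, 2\pi)$,
phases 7–8) and a radius $\mathcal N(r_K, \sigma_r)$ (negative draws
rejected and resampled), where $r_W = r_w^\ast$ and the NREM radii scale
by the fixed coefficients. Superposed interference: pure seeded-phase
sinusoids at 0.35 Hz (respiration, 0.02 µM), 1.1 Hz (cardiac, 0.02 µM —
deliberately above Nyquist at 1.81 Hz, so it aliases, as it would in the
instrument) and 0.005 Hz (drift, 0.05 µM), plus white noise (0.01 µM).
Defaults: $r_w^\ast = 1$ µM (arbitrary scale; the pipeline is
scale-covariant), $\sigma_r = 0.05\,r_w^\ast$, 8 channels at 1.81 Hz,
one ~543-sample (5-min) block per stage.

`generateTransitionRecording()` drives a noiseless base path from the
wakefulness sector (radius $0.9\,r_w^\ast$) linearly into the phase-7/8
sector (radius ramping to $1.3\,r_w^\ast$), adds the same noise, and
returns the ground-truth onset computed by brute force: the detection
predicate evaluated sample-by-sample on the noiseless path,
independently of the detector. `generateRawIntensity()` closes the loop
through the Beer–Lambert forward model, prepending an exactly-zero
baseline pad so the baseline-referenced inversion is exact.

What the generator does **not** emulate — and hence what passing tests
do not show about recorded data: hemodynamic response functions and
neurovascular dynamics (samples are i.i.d. within a stage, real series
are autocorrelated), motion artifacts, optode-coupling drift,
subject-to-subject variability beyond the seed, and any systematic
relation between stages other than the radius scaling itself. Tests on
this generator validate the *machinery* (geometry, criteria, metrics),
not clinical performance; the headline classification accuracies of the
motivating study require its non-public subject data and are explicitly
out of scope.

## Problem sizes and numerical tolerances used by the test suite

Identity checks run on $10^5$ random points (tolerance 1e-9); the
Beer–Lambert round trip on 8 channels × 218 samples (relative 1e-9);
ratio recovery on 20 seeds × 4 stages × 543 samples under the stated
5%-radial-noise condition (2% relative); detection on 20 seeded
transitions (onset within one 5-s window) and one $10^4$-window
wake-only recording with a 3-standard-deviation magnitude margin (zero
events); chance-rate and separability checks on 4000 and 400 windows of
10-fold CV. These sizes make the checks sharp while keeping the whole
suite around ten seconds on one core.

## Known limitations

* Absolute concentration scales depend on the pinned extinction/DPF
  choices; only ratios and threshold crossings are
  convention-independent.
* The cardiac band cannot be rejected at 1.81 Hz; it aliases to
  ~0.71 Hz and survives filtering. The implementation says so loudly
  rather than pretending otherwise.
* The arithmetic angle mean corrupts windows straddling the $2\pi$ wrap;
  the detection sector avoids the wrap, and a circular mean is one flag
  away.
* Event segmentation is maximal-run based; brief criterion dropouts
  split events. No debouncing is applied because none is specified.
* SNIRF support covers the continuous-wave amplitude subset only, via a
  bundled Python/h5py helper.
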
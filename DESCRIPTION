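Package: fnirsvpa
Title: Vector Phase Analysis of fNIRS Hemodynamics for Drowsiness and
    Sleep-Stage Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for vector phase analysis (VPA) of functional
    near-infrared spectroscopy (fNIRS) signals. Converts raw two-wavelength
    optical intensities to oxy-/deoxy-hemoglobin concentration changes via
    the modified Beer-Lambert law, removes physiological interference by
    Gaussian smoothing and band rejection, maps hemodynamics onto the
    octant-partitioned vector phase plane (HbO/HbR and the pi/4-rotated
    HbT/COE frame), calibrates wakefulness-based sleep-stage threshold
    circles, detects drowsiness from sliding-window angle and magnitude
    criteria, extracts windowed trajectory-slope and peak features, and
    evaluates multiclass sleep-stage classifiers under stratified
    cross-validation. Includes a seeded synthetic-data generator emulating
    stage-dependent cerebral-oxygen-regulation geometry so the full pipeline
    is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    MASS,
    rpart,
    class,
    randomForest,
    e1071,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'recording.R'
    'vpa.R'
    'features.R'
    'classify.R'
    'thresholds.R'
    'detection.R'
    'fnirsvpa-package.R'
    'io.R'
    'mbll.R'
    'preprocess.R'
    'pipeline.R'
    'snirf.R'
    'synth.R'
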
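#' @include AllClasses.R io.R mbll.R preprocess.R thresholds.R detection.R
#'   features.R classify.R synth.R
NULL

#' Consecutive labeled analysis windows from per-sample stage labels
#'
#' Chops the recording into non-overlapping windows of `windowSeconds`
#' and labels each by majority vote of its per-sample stage labels;
#' windows whose majority label is not one of W/N1/N2/N3 (e.g. a
#' transition segment) are dropped.
#'
#' @param labels per-sample factor of stage labels.
#' @param samplingRate Hz.
#' @param windowSeconds window width (default 5).
#' @return data.frame(start, end, label) of 1-based inclusive indices.
#' @export
makeStageWindows <- function(labels, samplingRate, windowSeconds = 5) {
  w <- ceiling(windowSeconds * samplingRate)
  n <- length(labels)
  starts <- seq.int(1L, n - w + 1L, by = w)
  out <- lapply(starts, function(s) {
    lab <- labels[s:(s + w - 1L)]
    tab <- table(lab)
    top <- names(tab)[which.max(tab)]
    if (!top %in% .STAGES || tab[[top]] <= w / 2) return(NULL)
    data.frame(start = s, end = s + w - 1L, label = top)
  })
  do.call(rbind, out)
}

#' Default pipeline configuration
#'
#' @param seed integer seed used by every stochastic stage.
#' @return nested list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 17L) {
  list(seed = as.integer(seed),
       input = NULL,                    # path to a recording CSV, or NULL
       input_kind = "hemodynamic",
       simulate = list(fs = 1.81, n_channels = 8, base_radius = 1.0),
       mbll = list(distance_cm = 2.1, dpf = 6.0, baseline_seconds = 30),
       filter = list(gauss_sigma_s = NULL, stopbands = "default"),
       baseline_window_s = NULL,        # e.g. c(0, 300); NULL = whole W data
       window_seconds = 5,
       detection = list(angle_low = 3 * pi / 4, circular = FALSE),
       classify = list(classifier = "knn", folds = 10))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [defaultPipelineConfig()] values.
#'
#' @param path YAML file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  stopifnot(file.exists(path))
  utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes convert (MBLL) -> filter -> trajectories -> calibrate ->
#' detect -> features -> classify, writing every artifact plus a JSON
#' manifest (package version, seed, input digests) into `outputDir`.
#' Without an input recording the configured synthetic generator supplies
#' a stage recording, so the whole chain runs end to end.
#'
#' @param config list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()], or a YAML path.
#' @param outputDir artifact directory (created if needed).
#' @return invisibly, a list with the in-memory artifacts (recording,
#'   thresholds, events, features, report, manifest).
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outputDir = tempfile("vpa_run_")) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(outputDir, f)
  manifest <- list(package = "fnirsvpa",
                   version = as.character(utils::packageVersion("fnirsvpa")),
                   seed = config$seed, artifacts = list())

  labels <- NULL
  if (is.null(config$input)) {
    sim <- .stage("simulate", {
      cfg <- synthConfig(seed = config$seed,
                         fs = config$simulate$fs,
                         nChannels = config$simulate$n_channels,
                         baseRadius = config$simulate$base_radius)
      generateStageRecording(cfg)
    })
    rec <- sim$recording
    labels <- sim$labels
  } else {
    rec <- .stage("read", readRecording(config$input, config$input_kind))
    manifest$input_md5 <- unname(tools::md5sum(config$input))
  }

  if (recordingKind(rec) == "raw") {
    rec <- .stage("convert", {
      params <- mbllParameters(distance = config$mbll$distance_cm,
                               dpf = config$mbll$dpf,
                               baselineSeconds = config$mbll$baseline_seconds)
      rawToHemodynamic(rec, params)
    })
  }

  rec <- .stage("filter", {
    bands <- if (identical(config$filter$stopbands, "default")) {
      defaultStopBands()
    } else {
      config$filter$stopbands
    }
    sigma <- config$filter$gauss_sigma_s
    if (is.null(sigma)) sigma <- 1.5 / samplingRate(rec)
    bandReject(gaussianSmooth(rec, sigma), bands)
  })
  writeRecording(rec, art("filtered.csv"))

  trajs <- .stage("trajectory", lapply(seq_len(ncol(rec)), function(ch) {
    buildTrajectory(rec, ch)
  }))

  thresholds <- .stage("calibrate", {
    bw <- config$baseline_window_s
    if (is.null(bw) && !is.null(labels)) {
      wIdx <- which(labels == "W")
      bw <- (range(wIdx) - 1L) / samplingRate(rec)
    }
    calibrateThresholds(rec, baselineWindow = bw)
  })
  writeThresholds(thresholds, art("thresholds.yaml"))

  events <- .stage("detect", {
    ev <- lapply(seq_along(trajs), function(ch) {
      detectDrowsiness(trajs[[ch]], thresholds[[ch]],
                       windowSeconds = config$window_seconds,
                       angleLow = config$detection$angle_low,
                       circular = config$detection$circular)
    })
    do.call(rbind, ev)
  })
  writeEvents(events, art("events.csv"))

  features <- report <- NULL
  if (!is.null(labels)) {
    features <- .stage("features", {
      win <- makeStageWindows(labels, samplingRate(rec),
                              config$window_seconds)
      tabs <- lapply(trajs, extractFeatures, windows = win)
      minmaxRescale(bindFeatureTables(tabs))
    })
    writeFeatures(features, art("features.csv"))
    report <- .stage("classify", {
      crossValidate(features, classifierSpec(config$classify$classifier),
                    folds = config$classify$folds, seed = config$seed)
    })
    jsonlite::write_json(
      list(classifier = report@classifier, folds = report@folds,
           accuracy = report@accuracy,
           confusion = unclass(report@confusion),
           metrics = report@metrics, auc = as.list(report@auc)),
      art("report.json"), auto_unbox = TRUE, digits = NA, na = "null")
  }

  files <- list.files(outputDir, full.names = TRUE)
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(recording = rec, thresholds = thresholds, events = events,
                 features = features, report = report,
                 manifest = manifest, outputDir = outputDir))
}
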
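#' @include AllClasses.R recording.R
#' @importFrom utils read.csv write.csv
NULL

## Canonical CSV dialect: UTF-8, '#'-prefixed key:value header block
## (subject, kind, sampling_rate_hz, channels, wavelengths_nm for raw),
## then a header row and one sample per row. '.' decimal separator.

.headerLines <- function(rec) {
  md <- metadata(rec)
  h <- c("# fnirsvpa recording v1",
         sprintf("# subject: %s", md$subject),
         sprintf("# kind: %s", md$kind),
         sprintf("# sampling_rate_hz: %.15g", md$sampling_rate),
         sprintf("# channels: %s", paste(colnames(rec), collapse = ",")))
  if (md$kind == "raw") {
    h <- c(h, sprintf("# wavelengths_nm: %s",
                      paste(md$wavelengths, collapse = ",")))
  }
  h
}

#' Write a recording to the canonical CSV dialect
#'
#' One sample per row; columns `time_s` plus `<channel>_<role>` where the
#' role is `hbo`/`hbr` (hemodynamic) or `wl<nm>` (raw). Metadata lives in
#' '#'-prefixed `key: value` lines above the header row. Values are
#' written with 17 significant digits so a read-back reproduces the
#' recording to full double precision.
#'
#' @param rec a [FnirsRecording-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "FnirsRecording"))
  cols <- list(time_s = sampleTimes(rec))
  for (nm in assayNames(rec)) {
    a <- assay(rec, nm)
    for (ch in colnames(rec)) cols[[paste0(ch, "_", nm)]] <- a[, ch]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.headerLines(rec), con)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

.parseHeader <- function(lines) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

#' Read a recording from the canonical CSV dialect
#'
#' Column order in the file is irrelevant: roles are resolved from the
#' column names. Timestamps must be uniform at the declared sampling rate
#' (relative tolerance 1e-6); every cell must be finite.
#'
#' @param path CSV file written by [writeRecording()] (or compatible).
#' @param kind optionally assert the expected kind (`"raw"` or
#'   `"hemodynamic"`); default accepts what the header declares.
#' @return a validated [FnirsRecording-class].
#' @export
readRecording <- function(path, kind = NULL) {
  if (!file.exists(path)) {
    stop("configuration error: no such recording file: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- .parseHeader(lines[startsWith(lines, "#")])
  for (need in c("kind", "sampling_rate_hz", "channels")) {
    if (is.null(hdr[[need]])) {
      stop(sprintf("format error: missing header field '%s'", need))
    }
  }
  fileKind <- hdr$kind
  if (!fileKind %in% c("raw", "hemodynamic")) {
    stop("format error: kind must be 'raw' or 'hemodynamic'")
  }
  if (!is.null(kind) && kind != fileKind) {
    stop(sprintf("format error: expected kind '%s' but file declares '%s'",
                 kind, fileKind))
  }
  fs <- as.numeric(hdr$sampling_rate_hz)
  if (!is.finite(fs) || fs <= 0) {
    stop("format error: sampling_rate_hz must be positive")
  }
  channels <- strsplit(hdr$channels, ",")[[1]]
  df <- read.csv(textConnection(lines[!startsWith(lines, "#")]),
                 check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("format error: missing time_s column")
  for (j in names(df)) {
    x <- df[[j]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      bad <- which(!is.numeric(x) | !is.finite(suppressWarnings(
        as.numeric(x))))[1]
      stop(sprintf("data error: non-finite/non-numeric value in column '%s'%s",
                   j, if (length(bad)) sprintf(", row %d", bad) else ""))
    }
  }
  t <- df$time_s
  if (length(t) > 1L && any(abs(diff(t) - 1 / fs) > 1e-6 / fs)) {
    stop("data error: timestamps are not uniform at the declared rate")
  }
  roles <- if (fileKind == "hemodynamic") {
    c("hbo", "hbr")
  } else {
    wl <- strsplit(hdr$wavelengths_nm %||% "", ",")[[1]]
    if (length(wl) != 2L) {
      stop("format error: raw recordings need wavelengths_nm with 2 values")
    }
    paste0("wl", wl)
  }
  a <- lapply(roles, function(role) {
    want <- paste0(channels, "_", role)
    miss <- setdiff(want, names(df))
    if (length(miss)) {
      stop(sprintf("format error: missing column(s) %s",
                   paste(miss, collapse = ", ")))
    }
    as.matrix(df[, want, drop = FALSE])
  })
  if (fileKind == "hemodynamic") {
    hemodynamicRecording(a[[1]], a[[2]], fs,
                         subject = hdr$subject %||% "unknown",
                         channelLabels = channels, startTime = t[1])
  } else {
    rawRecording(a[[1]], a[[2]], fs,
                 wavelengths = as.numeric(strsplit(hdr$wavelengths_nm,
                                                   ",")[[1]]),
                 subject = hdr$subject %||% "unknown",
                 channelLabels = channels, startTime = t[1])
  }
}

#' Write detection events / feature tables to CSV
#'
#' `writeEvents` writes the detection-event columns (channel, 0-based
#' onset sample, time, window mean angle and magnitude, crossed circle,
#' phase at crossing); an empty event set yields a header-only file.
#' `writeFeatures` writes the 9 feature columns plus label, channel and
#' window id.
#'
#' @param events detection-event data.frame from [detectDrowsiness()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEvents <- function(events, path) {
  cols <- c("channel", "onset_sample", "onset_time", "window_mean_angle",
            "window_mean_magnitude", "crossed_circle", "phase_at_crossing")
  if (is.null(events) || nrow(events) == 0L) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  write.csv(events[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @param table a [FeatureTable-class].
#' @export
writeFeatures <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  df <- cbind(table@features,
              label = as.character(table@label),
              channel = table@channel, window = table@window)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature CSV back into a FeatureTable
#'
#' @param path CSV written by [writeFeatures()].
#' @return a raw (unscaled) [FeatureTable-class].
#' @export
readFeatures <- function(path) {
  df <- read.csv(path)
  miss <- setdiff(c(.FEATURE_NAMES, "label"), names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  new("FeatureTable", features = df[, .FEATURE_NAMES],
      label = factor(df$label, levels = .STAGES),
      channel = as.integer(df$channel %||% rep(1L, nrow(df))),
      window = as.integer(df$window %||% seq_len(nrow(df))),
      scaled = FALSE, scaling = data.frame())
}

#' Write / read calibrated thresholds as YAML
#'
#' Per-channel mapping with r_w, r_n1, r_n2, r_n3 and n.
#'
#' @param thresholds list of [ThresholdSet-class] (one per channel).
#' @param path YAML path.
#' @return invisibly `path`; `readThresholds` returns the list.
#' @export
writeThresholds <- function(thresholds, path) {
  out <- lapply(thresholds, function(th) {
    list(channel = th@channel, r_w = th@rW, r_n1 = th@rN1, r_n2 = th@rN2,
         r_n3 = th@rN3, n = th@nBaseline)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    sleepStageRadii(x$r_w, n = x$n, channel = x$channel)
  })
}
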
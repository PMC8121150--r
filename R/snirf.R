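#' @include AllClasses.R recording.R io.R
NULL

## SNIRF is HDF5-based; the container is handled by a bundled Python
## helper (h5py) invoked through system2, limited to the continuous-wave
## amplitude subset.

.pythonBin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("SNIRF support needs a 'python' executable with h5py on the PATH")
}

.snirfHelper <- function() {
  system.file("python", "snirf_io.py", package = "fnirsvpa", mustWork = TRUE)
}

.runSnirfHelper <- function(args) {
  out <- suppressWarnings(system2(.pythonBin(), c(.snirfHelper(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop("SNIRF helper failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}

#' Write a raw recording as a SNIRF container
#'
#' Continuous-wave subset only: one measurement column per (channel,
#' wavelength), dataType 1 (CW amplitude).
#'
#' @param rec a raw [FnirsRecording-class].
#' @param path output `.snirf` path.
#' @return invisibly, `path`.
#' @export
writeSnirf <- function(rec, path) {
  stopifnot(is(rec, "FnirsRecording"), recordingKind(rec) == "raw")
  tmpMeta <- tempfile(fileext = ".json")
  tmpData <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmpMeta, tmpData)))
  md <- metadata(rec)
  jsonlite::write_json(list(sampling_rate = md$sampling_rate,
                            wavelengths = md$wavelengths,
                            n_channels = ncol(rec),
                            subject = md$subject),
                       tmpMeta, auto_unbox = TRUE, digits = NA)
  i1 <- intensityBlock(rec, 1L)
  i2 <- intensityBlock(rec, 2L)
  m <- matrix(0, nrow(rec), 2L * ncol(rec))
  m[, seq(1L, 2L * ncol(rec), by = 2L)] <- i1
  m[, seq(2L, 2L * ncol(rec), by = 2L)] <- i2
  utils::write.table(m, tmpData, sep = ",", row.names = FALSE,
                     col.names = paste0("c", rep(seq_len(ncol(rec)),
                                                 each = 2), "w", 1:2))
  .runSnirfHelper(c("write", tmpMeta, tmpData, path))
  invisible(path)
}

#' Read a continuous-wave SNIRF container
#'
#' Wavelength pairs are mapped onto the raw intensity block; channel ids
#' are assigned by (source, detector) pair in file order. Containers with
#' a wavelength count other than 2 or non-CW data types are rejected as
#' unsupported.
#'
#' @param path a `.snirf` file.
#' @return a raw [FnirsRecording-class].
#' @export
readSnirf <- function(path) {
  stopifnot(file.exists(path))
  tmpMeta <- tempfile(fileext = ".json")
  tmpData <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmpMeta, tmpData)))
  .runSnirfHelper(c("read", path, tmpMeta, tmpData))
  meta <- jsonlite::read_json(tmpMeta, simplifyVector = TRUE)
  m <- as.matrix(read.csv(tmpData))
  nc <- meta$n_channels
  i1 <- m[, seq(1L, 2L * nc, by = 2L), drop = FALSE]
  i2 <- m[, seq(2L, 2L * nc, by = 2L), drop = FALSE]
  rawRecording(i1, i2, meta$sampling_rate,
               wavelengths = as.numeric(meta$wavelengths),
               subject = if (nzchar(meta$subject)) meta$subject else "unknown")
}
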
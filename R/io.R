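# Plain-text interchange: one CSV per wavelength (row = channel, column =
# sample, header = sample times in seconds) plus a JSON metadata sidecar;
# behavioral trial tables and hemoglobin series as CSV.

#' Write a raw intensity record to the CSV dialect
#'
#' Emits `<id>_wl<λ>.csv` per wavelength (rows = channels, columns = samples,
#' header row = sample times in seconds) and `<id>_meta.json` with subject
#' metadata.
#'
#' @param raw A `fnirs_raw` record.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_intensity_csv <- function(raw, dir) {
  stopifnot(inherits(raw, "fnirs_raw"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- dim(raw$intensity)[3]
  times <- sprintf("t%.4f", (seq_len(nt) - 1) / raw$sampling_rate_hz)
  paths <- character(0)
  for (w in seq_along(raw$wavelengths_nm)) {
    p <- file.path(dir, sprintf("%s_wl%d.csv", raw$subject_id,
                                round(raw$wavelengths_nm[w])))
    m <- raw$intensity[w, , , drop = TRUE]
    colnames(m) <- times
    write.csv(m, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(raw$subject_id, "_meta.json"))
  jsonlite::write_json(list(subject_id = raw$subject_id, group = raw$group,
                            wavelengths_nm = raw$wavelengths_nm,
                            sampling_rate_hz = raw$sampling_rate_hz,
                            covariates = raw$covariates),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' Read a raw intensity record from the CSV dialect
#'
#' @param dir Directory holding the files written by [write_intensity_csv()].
#' @param subject_id Subject identifier (file prefix).
#' @return A `fnirs_raw` record.
#' @export
read_intensity_csv <- function(dir, subject_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(subject_id, "_meta.json")),
                              simplifyVector = TRUE)
  planes <- lapply(meta$wavelengths_nm, function(wl) {
    as.matrix(read.csv(file.path(dir, sprintf("%s_wl%d.csv", subject_id,
                                              round(wl)))))
  })
  nc <- nrow(planes[[1]]); nt <- ncol(planes[[1]])
  intensity <- array(0, dim = c(length(planes), nc, nt))
  for (w in seq_along(planes)) intensity[w, , ] <- planes[[w]]
  dimnames(intensity) <- list(as.character(round(meta$wavelengths_nm)),
                              NULL, NULL)
  structure(list(intensity = intensity,
                 wavelengths_nm = meta$wavelengths_nm,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 subject_id = meta$subject_id, group = meta$group,
                 covariates = as.list(meta$covariates)),
            class = "fnirs_raw")
}

#' Write a behavioral trial table as CSV
#' @param trials Trial table data frame.
#' @param path Output path.
#' @export
write_behavior_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
}

#' Read a behavioral trial table from CSV
#' @param path CSV written by [write_behavior_csv()].
#' @return The trial table data frame.
#' @export
read_behavior_csv <- function(path) {
  tt <- read.csv(path, stringsAsFactors = FALSE)
  tt$rt_ms[tt$response == "none"] <- NA_real_
  tt
}

#' Write a hemoglobin series (HbO/HbR) and its processing log
#'
#' @param hemo A `hemo_series`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_hemo_csv <- function(hemo, dir) {
  stopifnot(inherits(hemo, "hemo_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- if (is.null(hemo$subject_id)) "subject" else hemo$subject_id
  p1 <- file.path(dir, paste0(id, "_hbo.csv"))
  p2 <- file.path(dir, paste0(id, "_hbr.csv"))
  p3 <- file.path(dir, paste0(id, "_log.json"))
  write.csv(hemo$hbo, p1, row.names = FALSE)
  write.csv(hemo$hbr, p2, row.names = FALSE)
  jsonlite::write_json(hemo$processing_log, p3, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(p1, p2, p3))
}
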
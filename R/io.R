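# On-disk dialect: a plain-text CSV per participant x cue with a '# key:
# value' header block (participant_id, cue, fs_hz, calibration_factor),
# columns time_s, od_refraction_d, os_refraction_d (empty field = missing
# sample), plus a companion '<stem>_events.csv' with the stimulus log.

events_path_for <- function(path) {
  paste0(sub("\\.csv$", "", path), "_events.csv")
}

#' Write a recording to the plain-text CSV dialect
#'
#' Emits `<path>` with the header block and the two-eye refraction columns
#' (missing samples as empty fields), and `<stem>_events.csv` with the
#' stimulus event log. [read_recording()] round-trips the result
#' losslessly to within float text precision.
#'
#' @param rec An `accom_recording`.
#' @param path Output CSV path (the events file is written next to it).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  num <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))
  header <- c(
    sprintf("# participant_id: %s", rec$participant_id),
    sprintf("# cue: %s", rec$cue),
    sprintf("# fs_hz: %.9g", rec$fs),
    sprintf("# calibration_factor: %.9g", rec$calibration_factor)
  )
  body <- paste(sprintf("%.6f", rec$time), num(rec$od), num(rec$os), sep = ",")
  ok <- tryCatch({
    writeLines(c(header, "time_s,od_refraction_d,os_refraction_d", body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write recording to '%s'", path)
  ev <- rec$events
  ev_lines <- paste(ev$movement_index, ev$direction,
                    sprintf("%.6f", ev$onset_s),
                    sprintf("%.9g", ev$demand_start_d),
                    sprintf("%.9g", ev$demand_end_d), sep = ",")
  writeLines(c("movement_index,direction,onset_s,demand_start_d,demand_end_d",
               ev_lines), events_path_for(path))
  invisible(path)
}

#' Read a recording from the plain-text CSV dialect
#'
#' Parses the `# key: value` header block, the per-sample refraction
#' columns (empty fields become missing samples), and the companion
#' `<stem>_events.csv` event log. Malformed rows raise an error naming the
#' offending line.
#'
#' @param path Path to a recording CSV written by [write_recording()].
#' @return An `accom_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stopf("recording file not found: '%s'", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
    stopf("header lines ('# key: value') must come first in '%s'", path)
  meta <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stopf("malformed header at line %d of '%s': %s", i, path, lines[i])
    meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("participant_id", "cue", "fs_hz", "calibration_factor"))
    if (is.null(meta[[key]]))
      stopf("header of '%s' is missing '%s'", path, key)
  fs <- suppressWarnings(as.numeric(meta$fs_hz))
  if (is.na(fs) || fs <= 0) stopf("invalid fs_hz in '%s': %s", path, meta$fs_hz)
  calib <- suppressWarnings(as.numeric(meta$calibration_factor))
  if (is.na(calib) || calib <= 0)
    stopf("invalid calibration_factor in '%s'", path)

  body <- lines[-seq_len(length(hdr_idx) + 1L)]  # skip header block + column row
  first_data_line <- length(hdr_idx) + 2L
  nf <- lengths(strsplit(body, ",", fixed = TRUE))
  # a trailing empty field ("1.0,2.0,") splits to 2 pieces; count separators too
  nsep <- lengths(gregexpr(",", body, fixed = TRUE))
  bad <- which(nsep != 2L)
  if (length(bad))
    stopf("malformed data row at line %d of '%s' (expected 3 fields): %s",
          first_data_line + bad[1] - 1L, path, body[bad[1]])
  dat <- read.table(text = body, sep = ",", header = FALSE,
                    colClasses = "numeric", na.strings = "",
                    col.names = c("time_s", "od", "os"), fill = FALSE)
  if (anyNA(dat$time_s))
    stopf("missing time value at line %d of '%s'",
          first_data_line + which(is.na(dat$time_s))[1] - 1L, path)

  epath <- events_path_for(path)
  if (!file.exists(epath)) stopf("companion events file not found: '%s'", epath)
  ev <- read.table(epath, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  new_recording(participant_id = meta$participant_id, cue = meta$cue, fs = fs,
                time = dat$time_s, od = dat$od, os = dat$os,
                events = tibble::as_tibble(ev), calibration_factor = calib)
}

#' Write a cohort of recordings to a directory
#'
#' @param recs Named list of recordings (as from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written recording paths.
#' @export
write_cohort <- function(recs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%s.csv", rec$participant_id, rec$cue))
    write_recording(rec, paths[i])
  }
  invisible(paths)
}

#' Read every recording CSV in a directory
#'
#' @param dir Directory containing recording CSVs (events files are
#'   recognised by their `_events.csv` suffix and skipped).
#' @return Named list of `accom_recording` objects.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stopf("input directory not found: '%s'", dir)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("_events\\.csv$", files)]
  if (!length(files)) stopf("no recording CSVs found in '%s'", dir)
  recs <- lapply(files, read_recording)
  names(recs) <- vapply(recs, function(r) paste(r$participant_id, r$cue, sep = "_"),
                        character(1))
  recs
}
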
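# The accom_recording S3 class: one participant x cue session as recorded
# by the instrument — two-eye refraction vectors with NA missing markers,
# a stimulus event log, and header metadata.

new_recording <- function(participant_id, cue, fs, time, od, os, events,
                          calibration_factor = 1.0) {
  rec <- structure(list(
    participant_id = as.character(participant_id),
    cue = as.character(cue),
    fs = fs,
    time = as.numeric(time),
    od = as.numeric(od),
    os = as.numeric(os),
    events = events,
    calibration_factor = calibration_factor,
    signal = NULL,        # combined/processed signal, set by preprocess_recording
    interp_mask = NULL,   # provenance of gap interpolation
    substitutions = NULL  # per-eye substitution counts, set by substitute_eye
  ), class = "accom_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  n <- length(rec$time)
  if (length(rec$od) != n || length(rec$os) != n)
    stopf("od/os length (%d/%d) must equal time length (%d)",
          length(rec$od), length(rec$os), n)
  if (!assert_scalar_num(rec$fs, "fs") > 0) stopf("`fs` must be > 0")
  if (n >= 2L) {
    dt <- diff(rec$time)
    if (any(dt <= 0) || max(abs(dt - 1 / rec$fs)) > 1e-6)
      stopf("time must increase in strict 1/fs steps")
  }
  ev <- rec$events
  req <- c("movement_index", "direction", "onset_s", "demand_start_d",
           "demand_end_d")
  if (!all(req %in% names(ev)))
    stopf("events must have columns: %s", paste(req, collapse = ", "))
  if (nrow(ev) && (any(ev$onset_s < rec$time[1] - 1e-9) ||
                   any(ev$onset_s > rec$time[n] + 1e-9)))
    stopf("every event onset must lie within the recording span")
  if (nrow(ev) && !all(ev$direction %in% c("focus", "defocus")))
    stopf("event direction must be 'focus' or 'defocus'")
  invisible(rec)
}

#' @export
print.accom_recording <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<accom_recording> %s / %s: %d samples @ %g Hz (%.1f s), %d events\n",
              x$participant_id, x$cue, n, x$fs, n / x$fs, nrow(x$events)))
  miss <- c(od = mean(is.na(x$od)), os = mean(is.na(x$os)))
  cat(sprintf("  missing: OD %.1f%%, OS %.1f%%; calibration %.3g%s\n",
              100 * miss["od"], 100 * miss["os"], x$calibration_factor,
              if (is.null(x$signal)) "" else "; preprocessed"))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `accom_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$time)
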
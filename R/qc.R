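# File-level quality control: eye-substitution repair, missingness
# accounting, and the conservative rejection rules applied to each
# recording before any filtering.

#' Repair single-eye signal dropout by substitution
#'
#' Accommodation is consensual, so loss of signal in one eye is repaired by
#' copying the other eye's refraction at that sample. Samples missing in
#' both eyes remain missing. Samples where the target eye is valid are
#' never altered.
#'
#' @param rec An `accom_recording`.
#' @return The recording with substituted samples; `rec$substitutions`
#'   holds the per-eye substitution counts.
#' @export
substitute_eye <- function(rec) {
  stopifnot(inherits(rec, "accom_recording"))
  od_miss <- is.na(rec$od)
  os_miss <- is.na(rec$os)
  fill_od <- od_miss & !os_miss
  fill_os <- os_miss & !od_miss
  rec$od[fill_od] <- rec$os[fill_od]
  rec$os[fill_os] <- rec$od[fill_os]
  rec$substitutions <- c(od = sum(fill_od), os = sum(fill_os))
  rec
}

#' Fraction of missing samples in a recording
#'
#' Combined missingness: the fraction of samples missing in *both* eyes
#' (after [substitute_eye()] this equals each eye's missingness). With
#' `per_eye = TRUE` the OD/OS fractions are returned instead.
#'
#' @param rec An `accom_recording`, or a logical missing-sample mask.
#' @param per_eye Return per-eye fractions rather than the combined one.
#' @return Missing fraction(s) in `[0, 1]`.
#' @export
missing_fraction <- function(rec, per_eye = FALSE) {
  if (is.logical(rec)) {
    if (!length(rec)) stopf("zero-length mask")
    return(mean(rec))
  }
  stopifnot(inherits(rec, "accom_recording"))
  if (!n_samples(rec)) stopf("zero-length recording")
  if (per_eye)
    return(c(od = mean(is.na(rec$od)), os = mean(is.na(rec$os))))
  mean(is.na(rec$od) & is.na(rec$os))
}

#' Length of the longest consecutive missing-sample run
#'
#' @param mask Logical vector, `TRUE` = missing. An `accom_recording` may
#'   be given instead, in which case the combined (both eyes missing) mask
#'   is used.
#' @return Length of the longest `TRUE` run; 0 if none.
#' @examples
#' longest_missing_run(c(FALSE, TRUE, TRUE, FALSE, TRUE))  # 2
#' @export
longest_missing_run <- function(mask) {
  if (inherits(mask, "accom_recording"))
    mask <- is.na(mask$od) & is.na(mask$os)
  if (!is.logical(mask)) stopf("`mask` must be logical")
  if (!length(mask) || !any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Apply the file-level rejection rules
#'
#' A recording is rejected when, after eye substitution, (a) 25% or more of
#' its samples are missing (`DATA_LOSS_25PCT`), (b) fewer than 750 valid
#' samples — 15 s at 50 Hz — remain where a full session of about 7500 was
#' expected (`TOO_SHORT_750`), or (c) it contains a run of 225 or more
#' consecutive missing samples, i.e. 4.5 s (`GAP_225`). All thresholds are
#' inclusive as worded and configurable. Multiple reasons may co-occur;
#' the report's `reasons` field is empty iff the file is accepted.
#'
#' @param rec An `accom_recording`. By default [substitute_eye()] is
#'   applied first so the rules judge the repaired combined signal; set
#'   `presubstitution = TRUE` to judge each eye's raw union instead.
#' @param max_missing_frac Rejection threshold on the combined missing
#'   fraction (inclusive).
#' @param min_valid_samples Minimum number of valid (non-missing) samples.
#' @param max_gap Maximum tolerated consecutive missing run, exclusive
#'   (a run of exactly `max_gap` rejects).
#' @param expected_samples Nominal full-session length, reported as
#'   `completeness = n_valid / expected_samples` (metadata only, not a
#'   rejection rule).
#' @param presubstitution Evaluate the rules before eye substitution.
#' @return A `qc_report`: list with `n_samples`, `missing_fraction`,
#'   `missing_per_eye`, `longest_missing_run`, `n_valid`, `completeness`,
#'   `accepted`, `reasons`.
#' @export
apply_rejection <- function(rec,
                            max_missing_frac = 0.25,
                            min_valid_samples = 750L,
                            max_gap = 225L,
                            expected_samples = 7500L,
                            presubstitution = FALSE) {
  stopifnot(inherits(rec, "accom_recording"))
  judged <- if (presubstitution) rec else substitute_eye(rec)
  # post-substitution a sample is missing iff both eyes are; without the
  # repair a sample with either eye missing counts as compromised
  miss <- if (presubstitution) is.na(judged$od) | is.na(judged$os)
          else is.na(judged$od) & is.na(judged$os)
  n <- length(miss)
  if (!n) stopf("zero-length recording")
  frac <- mean(miss)
  n_valid <- n - sum(miss)
  gap <- longest_missing_run(miss)
  reasons <- character(0)
  if (frac >= max_missing_frac) reasons <- c(reasons, "DATA_LOSS_25PCT")
  if (n_valid < min_valid_samples) reasons <- c(reasons, "TOO_SHORT_750")
  if (gap >= max_gap) reasons <- c(reasons, "GAP_225")
  structure(list(
    participant_id = rec$participant_id,
    cue = rec$cue,
    n_samples = n,
    missing_fraction = frac,
    missing_per_eye = c(od = mean(is.na(judged$od)), os = mean(is.na(judged$os))),
    longest_missing_run = gap,
    n_valid = n_valid,
    completeness = n_valid / expected_samples,
    accepted = length(reasons) == 0L,
    reasons = sort(reasons)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s / %s: %s\n", x$participant_id, x$cue,
              if (x$accepted) "ACCEPTED" else
                paste("REJECTED:", paste(x$reasons, collapse = ", "))))
  cat(sprintf("  %d samples, %.1f%% missing, longest gap %d, %d valid (%.0f%% of expected)\n",
              x$n_samples, 100 * x$missing_fraction, x$longest_missing_run,
              x$n_valid, 100 * x$completeness))
  invisible(x)
}

# Linear interpolation across interior NA runs of a numeric vector;
# leading/trailing runs take the nearest valid value. Runs of length
# >= max_gap are left missing (such files should already be rejected).
interpolate_gaps_vec <- function(x, max_gap = 225L) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (all(miss)) stopf("no valid samples to interpolate from")
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_na <- rep(FALSE, length(x))
  for (k in which(r$values & r$lengths >= max_gap))
    keep_na[starts[k]:ends[k]] <- TRUE
  idx <- which(!miss)
  filled <- approx(idx, x[idx], xout = seq_along(x), method = "linear",
                   rule = 2)$y
  out <- ifelse(miss & !keep_na, filled, x)
  out[keep_na] <- NA_real_
  out
}

#' Interpolate short missing-sample gaps
#'
#' Fills gaps shorter than `max_gap` samples by linear interpolation
#' between the flanking valid samples; leading and trailing gaps take the
#' nearest valid value. The original missing mask is retained in
#' `rec$interp_mask` for provenance (movement windows with a high
#' interpolated fraction are later flagged `ARTIFACT`). Intended for
#' recordings already accepted by [apply_rejection()]; gaps at or above
#' `max_gap` are left missing.
#'
#' @param rec An `accom_recording` (ideally after [substitute_eye()]).
#' @param max_gap Gaps of this many samples or more are not filled.
#' @return The recording with both eyes gap-filled and `interp_mask` set.
#' @export
interpolate_short_gaps <- function(rec, max_gap = 225L) {
  stopifnot(inherits(rec, "accom_recording"))
  mask <- is.na(rec$od) | is.na(rec$os)
  rec$od <- interpolate_gaps_vec(rec$od, max_gap)
  rec$os <- interpolate_gaps_vec(rec$os, max_gap)
  rec$interp_mask <- mask
  rec
}
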
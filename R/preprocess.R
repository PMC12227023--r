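# Preprocessing chain. Fixed order: interpolate -> filter -> calibrate ->
# align -> segment -> differentiate. Filtering is applied to the whole
# recording before segmentation so 5-s windows carry no filter edge
# artifacts.

#' Zero-phase low-pass Butterworth filter
#'
#' Designs an `order`-th order Butterworth low-pass at cut-off `fc` and
#' applies it forward-backward (zero phase), so the filter adds no group
#' delay that would bias peak-velocity timing. The squared magnitude
#' response this implies puts the cut-off at -6 dB (amplitude 0.5) instead
#' of the single-pass -3 dB. DC gain is exactly 1 (the signal is demeaned
#' around the filter and restored), and edges are stabilised by
#' odd-reflection padding before the forward-backward pass.
#'
#' @param x Gap-free numeric signal.
#' @param fs Sampling rate (Hz).
#' @param order Filter order (default 5).
#' @param fc Cut-off frequency (Hz); must be below the Nyquist rate.
#' @return Filtered signal, same length as `x`.
#' @examples
#' lowpass_filter(rep(2, 100))           # constant in, constant out
#' @export
lowpass_filter <- function(x, fs = 50, order = 5, fc = 20) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(fc, "fc", positive = TRUE)
  if (fc >= fs / 2)
    stopf("cut-off fc = %g Hz must be below the Nyquist rate %g Hz", fc, fs / 2)
  if (anyNA(x)) stopf("signal must be gap-free before filtering")
  n <- length(x)
  if (n < 2L) return(x)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  np <- min(n - 1L, max(3L * (order + 1L), 50L))
  pre <- 2 * xc[1] - xc[(np + 1L):2L]
  post <- 2 * xc[n] - xc[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(pre, xc, post))
  y[(np + 1L):(np + n)] + mu
}

#' Apply the instrument calibration factor
#'
#' Photorefraction slopes vary between individuals (notably by race); the
#' recorded refraction is multiplied by a per-recording scalar to convert
#' instrument units to diopters.
#'
#' @param x Numeric signal.
#' @param factor Calibration scalar, > 0.
#' @return `x * factor`.
#' @export
apply_calibration <- function(x, factor) {
  assert_scalar_num(factor, "factor", positive = TRUE)
  x * factor
}

#' Align a signal to its first sample
#'
#' Subtracts the first recorded value from every sample so the trace shows
#' the *change* in refraction from its starting state; the output always
#' begins at exactly 0 and the operation is idempotent.
#'
#' @param x Non-empty numeric signal.
#' @return Baseline-aligned signal.
#' @examples
#' align_baseline(c(2.1, 2.4, 3.6))  # 0.0 0.3 1.5
#' @export
align_baseline <- function(x) {
  if (!length(x)) stopf("cannot align an empty signal")
  x - x[1]
}

#' Differentiate a refraction trace
#'
#' Central differences for interior samples,
#' `v[k] = (x[k+1] - x[k-1]) * fs / 2`, with one-sided differences at the
#' two edges. Exact for linear and (interior) quadratic signals.
#'
#' @param x Filtered, aligned refraction signal (length >= 3).
#' @param fs Sampling rate (Hz).
#' @return Velocity signal in D/s, same length as `x`.
#' @export
compute_velocity <- function(x, fs = 50) {
  n <- length(x)
  if (n < 3L) stopf("need at least 3 samples to differentiate (got %d)", n)
  assert_scalar_num(fs, "fs", positive = TRUE)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2L)]) / 2, x[n] - x[n - 1L]) * fs
}

#' Preprocess a recording into an analysis-ready signal
#'
#' Runs the per-recording part of the chain on the combined two-eye signal:
#' eye substitution, short-gap interpolation, zero-phase low-pass
#' filtering, and calibration. The processed signal is stored in
#' `rec$signal`; the two eyes are averaged after substitution (samples
#' missing in both eyes are interpolated like any other gap).
#'
#' @param rec An `accom_recording`.
#' @param fc,order Low-pass cut-off (Hz) and filter order.
#' @param max_gap Gap-interpolation ceiling in samples (see
#'   [interpolate_short_gaps()]).
#' @param calibration Optional calibration override; defaults to the
#'   recording's header value.
#' @return The recording with `signal` and `interp_mask` populated.
#' @export
preprocess_recording <- function(rec, fc = 20, order = 5, max_gap = 225L,
                                 calibration = NULL) {
  stopifnot(inherits(rec, "accom_recording"))
  rec <- substitute_eye(rec)
  rec <- interpolate_short_gaps(rec, max_gap = max_gap)
  combined <- (rec$od + rec$os) / 2
  if (anyNA(combined))
    combined <- interpolate_gaps_vec(combined, max_gap = .Machine$integer.max)
  filtered <- lowpass_filter(combined, fs = rec$fs, order = order, fc = fc)
  factor <- calibration %||% rec$calibration_factor
  rec$signal <- apply_calibration(filtered, factor)
  rec
}

#' Segment a recording into per-movement traces
#'
#' Cuts one window of `duration` seconds per stimulus event, starting at
#' the event's `onset_s`, from the preprocessed signal (the recording is
#' passed through [preprocess_recording()] first if needed). Each window
#' is baseline-aligned to its first sample, differentiated, and labeled
#' with the event's direction. Windows that would extend past the end of
#' the recording are dropped; the number dropped is attached as the
#' `"n_dropped"` attribute.
#'
#' @param rec An accepted, gap-filled `accom_recording` with a non-empty
#'   event log.
#' @param duration Window length in seconds (protocol: 5 s, 250 samples).
#' @param ... Passed to [preprocess_recording()] when the recording has not
#'   been preprocessed yet.
#' @return List of `movement_trace` objects with refraction (aligned
#'   change, D), velocity (D/s) and the interpolated fraction of the
#'   window; attribute `n_dropped` counts out-of-range events.
#' @export
segment_movements <- function(rec, duration = 5, ...) {
  stopifnot(inherits(rec, "accom_recording"))
  if (!nrow(rec$events)) stopf("recording has an empty event log")
  if (is.null(rec$signal)) rec <- preprocess_recording(rec, ...)
  win_n <- seconds_to_samples(duration, rec$fs)
  n <- n_samples(rec)
  demand_step <- abs(rec$events$demand_end_d - rec$events$demand_start_d)
  interp <- rec$interp_mask %||% rep(FALSE, n)
  traces <- vector("list", nrow(rec$events))
  dropped <- 0L
  for (i in seq_len(nrow(rec$events))) {
    start <- as.integer(round(rec$events$onset_s[i] * rec$fs)) + 1L
    end <- start + win_n - 1L
    if (start < 1L || end > n) {
      dropped <- dropped + 1L
      next
    }
    x <- align_baseline(rec$signal[start:end])
    traces[[i]] <- new_movement_trace(
      t = (seq_len(win_n) - 1L) / rec$fs,
      refraction = x,
      velocity = compute_velocity(x, rec$fs),
      direction = rec$events$direction[i],
      fs = rec$fs,
      participant_id = rec$participant_id,
      cue = rec$cue,
      demand_step = demand_step[i],
      interp_frac = mean(interp[start:end])
    )
  }
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (dropped)
    warning(sprintf("%d event window(s) extended past end of recording and were dropped",
                    dropped), call. = FALSE)
  attr(traces, "n_dropped") <- dropped
  traces
}

#' Average traces after aligning them at their peak-velocity sample
#'
#' Because onset delays are randomized, naive pointwise averaging smears
#' the group response. Each trace is therefore time-shifted so its
#' peak-velocity sample maps to a common index before averaging; the
#' output is trimmed to the region covered by every trace.
#'
#' @param traces Non-empty list of `movement_trace` objects with a common
#'   sampling rate.
#' @return A tibble with `rel_t` (seconds relative to peak velocity),
#'   `mean_pos`, `sd_pos`, `mean_vel`, `sd_vel` and `n` (number of traces;
#'   a single trace yields itself with zero SD).
#' @export
align_at_peak_velocity <- function(traces) {
  if (!length(traces)) stopf("need at least one trace")
  stopifnot(all(vapply(traces, inherits, logical(1), "movement_trace")))
  fs <- traces[[1]]$fs
  if (any(abs(vapply(traces, `[[`, numeric(1), "fs") - fs) > 1e-9))
    stopf("all traces must share one sampling rate")
  k_pv <- vapply(traces, function(tr) {
    v <- tr$velocity %||% compute_velocity(tr$refraction, tr$fs)
    if (tr$direction == "focus") which.max(v) else which.min(v)
  }, integer(1))
  lens <- vapply(traces, function(tr) length(tr$refraction), integer(1))
  lo <- -(min(k_pv) - 1L)           # common window, relative to the peak sample
  hi <- min(lens - k_pv)
  rel <- lo:hi
  pos <- vapply(seq_along(traces), function(i)
    traces[[i]]$refraction[k_pv[i] + rel], numeric(length(rel)))
  vel <- vapply(seq_along(traces), function(i) {
    v <- traces[[i]]$velocity %||% compute_velocity(traces[[i]]$refraction, fs)
    v[k_pv[i] + rel]
  }, numeric(length(rel)))
  pos <- matrix(pos, nrow = length(rel))
  vel <- matrix(vel, nrow = length(rel))
  row_sd <- function(m) if (ncol(m) < 2L) rep(0, nrow(m)) else apply(m, 1L, sd)
  tibble::tibble(
    rel_t = rel / fs,
    mean_pos = rowMeans(pos), sd_pos = row_sd(pos),
    mean_vel = rowMeans(vel), sd_vel = row_sd(vel),
    n = length(traces)
  )
}
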
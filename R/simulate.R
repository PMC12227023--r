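#' Configuration for a synthetic step-response cohort
#'
#' Collects every knob of the synthetic-cohort generator. Defaults emulate
#' the experimental protocol: 50 Hz sampling, 5-s movements, a 1.5 D demand
#' step between 40 cm (2.5 D) and 1 m (1.0 D), 15 far-to-near + 15
#' near-to-far movements interleaved per cue session (doubled for monocular
#' cues), randomized 0.5-2 s onset delays, and per-cue final-amplitude
#' gains from [default_gain_table()].
#'
#' Values the protocol does not fix (response time constants, noise level,
#' amplitude jitter, blink/dropout rates) are synthetic conventions chosen
#' to look physiologic; see the methods vignette for the rationale.
#'
#' @param n_participants Number of simulated participants.
#' @param fs Sampling rate in Hz.
#' @param movement_duration Length of one movement slot in seconds. The
#'   randomized onset delay falls inside this slot, so a 30-movement session
#'   spans exactly `30 * movement_duration` seconds.
#' @param demand_near,demand_far Accommodative demand (D) of the near and
#'   far targets; their difference is the stimulated step.
#' @param gains Named numeric vector mapping cue codes to expected
#'   final-amplitude gain (FA / demand step), all in `[0, 1.2]`.
#' @param defocus_gains Gains for near-to-far movements; defaults to `gains`
#'   (defocus responses simulated as sign-flipped focus responses).
#' @param noise_sd Per-sample measurement noise sd (D), per eye.
#' @param tau_range Range of the per-movement response time constant (s),
#'   drawn uniformly; the default spans peak velocities of roughly 4-8 D/s
#'   at a 1.5 D amplitude.
#' @param onset_delay_range Range of the randomized stimulus onset delay (s)
#'   within each movement slot.
#' @param amplitude_sd Per-movement amplitude jitter sd (D) around the
#'   cue's target amplitude.
#' @param gap_rate Per-sample probability that a missing-data gap (blink /
#'   tracking dropout) starts, independently per eye. 0 disables artifacts.
#' @param gap_mean_length Mean gap length in samples (geometric).
#' @param calibration_factor Instrument calibration scalar recorded in the
#'   file header and applied during preprocessing.
#' @param seed Master seed; per-participant and per-movement streams are
#'   derived from it deterministically, so identical configs give
#'   byte-identical cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_movement()]
#' @export
sim_config <- function(n_participants = 20,
                       fs = 50,
                       movement_duration = 5,
                       demand_near = 2.5,
                       demand_far = 1.0,
                       gains = default_gain_table(),
                       defocus_gains = NULL,
                       noise_sd = 0.1,
                       tau_range = c(0.20, 0.35),
                       onset_delay_range = c(0.5, 2.0),
                       amplitude_sd = 0.05,
                       gap_rate = 0.001,
                       gap_mean_length = 12,
                       calibration_factor = 1.0,
                       seed = 1L) {
  assert_scalar_num(n_participants, "n_participants", positive = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(movement_duration, "movement_duration", positive = TRUE)
  assert_scalar_num(demand_near, "demand_near", positive = TRUE)
  assert_scalar_num(demand_far, "demand_far", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd")
  assert_scalar_num(amplitude_sd, "amplitude_sd")
  assert_scalar_num(gap_rate, "gap_rate")
  assert_scalar_num(gap_mean_length, "gap_mean_length", positive = TRUE)
  assert_scalar_num(calibration_factor, "calibration_factor", positive = TRUE)
  assert_scalar_num(seed, "seed")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (gap_rate < 0 || gap_rate >= 1) stopf("`gap_rate` must be in [0, 1)")
  missing_cues <- setdiff(CUE_CODES, names(gains))
  if (length(missing_cues))
    stopf("`gains` is missing cue(s): %s", paste(missing_cues, collapse = ", "))
  if (any(gains < 0) || any(gains > 1.2))
    stopf("all gains must lie in [0, 1.2]")
  if (length(tau_range) != 2L || any(tau_range <= 0) || diff(tau_range) < 0)
    stopf("`tau_range` must be an increasing pair of positive values")
  if (length(onset_delay_range) != 2L || any(onset_delay_range < 0) ||
      diff(onset_delay_range) < 0)
    stopf("`onset_delay_range` must be an increasing pair of non-negative values")
  if (max(onset_delay_range) >= movement_duration)
    stopf("onset delays must fall inside the movement slot")
  structure(list(
    n_participants = as.integer(n_participants),
    fs = fs,
    movement_duration = movement_duration,
    demand_near = demand_near,
    demand_far = demand_far,
    demand_step = demand_near - demand_far,
    gains = gains[CUE_CODES],
    defocus_gains = (defocus_gains %||% gains)[CUE_CODES],
    noise_sd = noise_sd,
    tau_range = tau_range,
    onset_delay_range = onset_delay_range,
    amplitude_sd = amplitude_sd,
    gap_rate = gap_rate,
    gap_mean_length = gap_mean_length,
    calibration_factor = calibration_factor,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants, %g Hz, %g-s movements, %.2f D step\n",
              x$n_participants, x$fs, x$movement_duration, x$demand_step))
  cat(sprintf("  noise_sd %.3g D, gap_rate %.3g, seed %d\n",
              x$noise_sd, x$gap_rate, x$seed))
  cat("  gains:", paste(sprintf("%s=%.2f", names(x$gains), x$gains),
                        collapse = " "), "\n")
  invisible(x)
}

# Noiseless first-order step response: baseline before onset, exponential
# approach to baseline + amplitude afterwards. `sign` is +1 (focus,
# far-to-near, accommodation increasing) or -1 (defocus).
step_response <- function(t, amplitude, tau, onset, baseline = 0, sign = 1,
                          pulse_height = 0, pulse_width = 0) {
  x <- rep(baseline, length(t))
  after <- t >= onset
  x[after] <- baseline + sign * amplitude * (1 - exp(-(t[after] - onset) / tau))
  if (pulse_height != 0 && pulse_width > 0) {
    # optional preprogrammed "pulse": a boxcar added to the velocity trace,
    # i.e. a ramp of slope pulse_height over [onset, onset + pulse_width]
    x[after] <- x[after] + sign * pulse_height * pmin(t[after] - onset, pulse_width)
  }
  x
}

#' Simulate a single accommodative step-response movement
#'
#' Generates one 5-s refraction trace: constant baseline until the onset
#' delay, then a first-order exponential approach to `baseline +/-
#' amplitude` with time constant `tau` (sign set by `direction`), plus
#' additive Gaussian measurement noise. The theoretical peak velocity of
#' the noiseless response is `amplitude / tau` at onset. An optional
#' preprogrammed "pulse" component (a boxcar added to the velocity trace)
#' is available for dual-mode experiments and off by default; note it
#' shifts the settled level by `pulse_height * pulse_width`.
#'
#' @param amplitude Response amplitude (D), >= 0.
#' @param tau Time constant (s), > 0.
#' @param onset Onset delay within the trace (s); the protocol randomizes
#'   this in `[0.5, 2]`.
#' @param direction `"focus"` (far-to-near, refraction increasing) or
#'   `"defocus"` (near-to-far).
#' @param baseline Pre-movement refraction level (D).
#' @param noise_sd Measurement noise sd (D); 0 gives the noiseless response.
#' @param fs Sampling rate (Hz).
#' @param duration Trace length (s); `duration * fs` must be >= 50 samples.
#' @param seed Optional seed; the same seed reproduces the trace exactly.
#' @param pulse_height,pulse_width Optional boxcar velocity pulse (D/s, s).
#' @return A `movement_trace` object: list with `t`, `refraction`,
#'   `direction`, `fs` and provenance fields. Velocity is not yet computed
#'   (see [compute_velocity()] / [segment_movements()]).
#' @examples
#' tr <- simulate_movement(1.5, tau = 0.25, onset = 1, noise_sd = 0)
#' tail(tr$refraction, 1)  # ~ 1.5 after 16 time constants
#' @export
simulate_movement <- function(amplitude, tau, onset,
                              direction = c("focus", "defocus"),
                              baseline = 0, noise_sd = 0,
                              fs = 50, duration = 5, seed = NULL,
                              pulse_height = 0, pulse_width = 0) {
  direction <- match.arg(direction)
  assert_scalar_num(amplitude, "amplitude")
  if (amplitude < 0) stopf("`amplitude` must be >= 0")
  assert_scalar_num(tau, "tau", positive = TRUE)
  assert_scalar_num(onset, "onset")
  if (onset < 0 || onset >= duration) stopf("`onset` must lie in [0, duration)")
  assert_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  n <- seconds_to_samples(duration, fs)
  if (n < 50L) stopf("duration * fs must be at least 50 samples (got %d)", n)
  t <- (seq_len(n) - 1L) / fs
  sgn <- if (direction == "focus") 1 else -1
  x <- step_response(t, amplitude, tau, onset, baseline, sgn,
                     pulse_height, pulse_width)
  if (noise_sd > 0)
    x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  new_movement_trace(t = t, refraction = x, direction = direction, fs = fs,
                     onset = onset)
}

new_movement_trace <- function(t, refraction, direction, fs,
                               velocity = NULL, participant_id = NA_character_,
                               cue = NA_character_, demand_step = NA_real_,
                               interp_frac = 0, onset = NA_real_) {
  structure(list(
    participant_id = participant_id, cue = cue, direction = direction,
    t = t, refraction = refraction, velocity = velocity, fs = fs,
    demand_step = demand_step, interp_frac = interp_frac, onset = onset
  ), class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace> %s, %d samples @ %g Hz%s\n",
              x$direction, length(x$refraction), x$fs,
              if (is.na(x$cue)) "" else sprintf(" [%s %s]", x$participant_id, x$cue)))
  invisible(x)
}

#' Inject blink/dropout gaps into a signal
#'
#' Replaces randomly placed runs of samples with `NA`, emulating the
#' non-response, blink and tracking-loss artifacts of video photorefraction.
#' Gap starts are independent Bernoulli events per sample; gap lengths are
#' geometric with mean `gap_mean_length`. With a fixed `seed` the gap
#' pattern is reproducible; `gap_rate = 0` returns the input unchanged.
#'
#' @param x A numeric vector, a `movement_trace`, or an `accom_recording`
#'   (gaps drawn independently for each eye).
#' @param gap_rate Per-sample probability that a gap starts.
#' @param gap_mean_length Mean gap length in samples.
#' @param seed Optional seed for reproducible gap placement.
#' @return Object of the same type with `NA` runs inserted; the number of
#'   missing samples is available via [missing_fraction()].
#' @export
inject_artifacts <- function(x, gap_rate, gap_mean_length = 12, seed = NULL) {
  UseMethod("inject_artifacts")
}

#' @export
inject_artifacts.numeric <- function(x, gap_rate, gap_mean_length = 12,
                                     seed = NULL) {
  assert_scalar_num(gap_rate, "gap_rate")
  if (gap_rate < 0 || gap_rate >= 1) stopf("`gap_rate` must be in [0, 1)")
  if (gap_rate == 0) return(x)
  assert_scalar_num(gap_mean_length, "gap_mean_length", positive = TRUE)
  n <- length(x)
  with_seed(seed, {
    starts <- which(runif(n) < gap_rate)
    if (length(starts)) {
      lens <- 1L + rgeom(length(starts), prob = 1 / gap_mean_length)
      for (i in seq_along(starts)) {
        idx <- starts[i]:min(starts[i] + lens[i] - 1L, n)
        x[idx] <- NA_real_
      }
    }
  })
  x
}

#' @export
inject_artifacts.movement_trace <- function(x, gap_rate, gap_mean_length = 12,
                                            seed = NULL) {
  x$refraction <- inject_artifacts(x$refraction, gap_rate, gap_mean_length, seed)
  x
}

#' @export
inject_artifacts.accom_recording <- function(x, gap_rate, gap_mean_length = 12,
                                             seed = NULL) {
  x$od <- inject_artifacts(x$od, gap_rate, gap_mean_length,
                           if (is.null(seed)) NULL else derive_seed(seed, 1L))
  x$os <- inject_artifacts(x$os, gap_rate, gap_mean_length,
                           if (is.null(seed)) NULL else derive_seed(seed, 2L))
  x
}

# One participant x cue session. Movements occupy consecutive 5-s slots;
# the randomized onset delay falls inside each slot, so the event log's
# onset_s is the slot start and a 30-movement session is exactly 150 s
# (7500 samples at 50 Hz). The refraction state carries over between
# movements (a focus step rises from the current level, the following
# defocus step falls back), as in a continuous recording.
simulate_recording <- function(participant_id, cue, config, seed = NULL) {
  cue <- match.arg(cue, CUE_CODES)
  n_mov <- cue_movement_count(cue)
  fs <- config$fs
  slot_n <- seconds_to_samples(config$movement_duration, fs)
  n <- n_mov * slot_n
  step <- config$demand_step

  with_seed(seed, {
    directions <- rep(c("focus", "defocus"), length.out = n_mov)
    delays <- runif(n_mov, config$onset_delay_range[1], config$onset_delay_range[2])
    taus <- runif(n_mov, config$tau_range[1], config$tau_range[2])
    gain <- unname(config$gains[cue])
    dgain <- unname(config$defocus_gains[cue])
    amp_target <- ifelse(directions == "focus", gain * step, dgain * step)
    amps <- pmax(0, amp_target + rnorm(n_mov, 0, config$amplitude_sd))

    signal <- numeric(n)
    state <- config$demand_far + rnorm(1, 0, 0.3)  # resting refraction near far demand
    t_slot <- (seq_len(slot_n) - 1L) / fs
    for (i in seq_len(n_mov)) {
      sgn <- if (directions[i] == "focus") 1 else -1
      xs <- step_response(t_slot, amps[i], taus[i], delays[i], state, sgn)
      signal[((i - 1L) * slot_n + 1L):(i * slot_n)] <- xs
      state <- xs[slot_n]
    }
    od <- signal + rnorm(n, 0, config$noise_sd)
    os <- signal + rnorm(n, 0, config$noise_sd)

    events <- tibble::tibble(
      movement_index = seq_len(n_mov),
      direction = directions,
      onset_s = (seq_len(n_mov) - 1L) * config$movement_duration,
      demand_start_d = ifelse(directions == "focus", config$demand_far,
                              config$demand_near),
      demand_end_d = ifelse(directions == "focus", config$demand_near,
                            config$demand_far)
    )
    rec <- new_recording(
      participant_id = participant_id, cue = cue, fs = fs,
      time = (seq_len(n) - 1L) / fs, od = od, os = os, events = events,
      calibration_factor = config$calibration_factor
    )
    if (config$gap_rate > 0)
      rec <- inject_artifacts(rec, config$gap_rate, config$gap_mean_length,
                              seed = derive_seed(seed %||% 0L, 999L))
    rec
  })
}

#' Simulate a full cohort of step-response recordings
#'
#' Generates one recording per participant and cue condition with the
#' protocol's movement counts (30 per binocular cue, 60 per monocular cue,
#' focus and defocus interleaved). Per-movement response amplitudes are
#' centred on `gain * demand_step` for each cue, so the population mean
#' final amplitude per cue equals its gain target. Per-participant seeds
#' are derived deterministically from the master seed: the same `config`
#' reproduces the cohort exactly.
#'
#' @param config A [sim_config()].
#' @param cues Cue codes to simulate (default: all seven).
#' @return A named list of `accom_recording` objects
#'   (`"<participant>_<cue>"`).
#' @examples
#' recs <- simulate_cohort(sim_config(n_participants = 2, seed = 7),
#'                         cues = "BDP")
#' length(recs)  # 2 recordings, 30 movements each
#' @export
simulate_cohort <- function(config, cues = CUE_CODES) {
  stopifnot(inherits(config, "sim_config"))
  cues <- match.arg(cues, CUE_CODES, several.ok = TRUE)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  recs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(cues)) {
      seed_ij <- derive_seed(config$seed,
                             i * 100L + match(cues[j], CUE_CODES))
      rec <- simulate_recording(ids[i], cues[j], config, seed = seed_ij)
      recs[[paste(ids[i], cues[j], sep = "_")]] <- rec
    }
  }
  recs
}
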
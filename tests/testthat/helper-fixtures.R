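# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A recording built directly from vectors, bypassing the simulator.
make_recording <- function(od, os = od, fs = 50, participant_id = "T01",
                           cue = "BDP", events = NULL,
                           calibration_factor = 1.0) {
  n <- length(od)
  if (is.null(events))
    events <- tibble::tibble(
      movement_index = 1L, direction = "focus", onset_s = 0,
      demand_start_d = 1.0, demand_end_d = 2.5
    )
  accomstep:::new_recording(
    participant_id = participant_id, cue = cue, fs = fs,
    time = (seq_len(n) - 1L) / fs, od = od, os = os, events = events,
    calibration_factor = calibration_factor
  )
}

# A recording with a prescribed missing pattern (indices set NA in both
# eyes) around a smooth base signal, sized to pass/fail specific QC rules.
make_masked_recording <- function(n, missing_idx = integer(0), fs = 50) {
  base <- 1.5 + 0.2 * sin(2 * pi * 0.1 * (seq_len(n) - 1) / fs)
  od <- os <- base
  od[missing_idx] <- NA_real_
  os[missing_idx] <- NA_real_
  make_recording(od, os, fs = fs)
}

# A bare movement trace from a refraction vector (velocity computed).
make_trace <- function(x, direction = "focus", fs = 50, interp_frac = 0,
                       demand_step = 1.5) {
  accomstep:::new_movement_trace(
    t = (seq_along(x) - 1) / fs, refraction = x,
    velocity = compute_velocity(x, fs), direction = direction, fs = fs,
    demand_step = demand_step, interp_frac = interp_frac
  )
}

# Evenly spread single missing samples (never adjacent) for mask fixtures.
spread_missing <- function(n, k) {
  stopifnot(2 * k <= n)
  seq(1L, by = 2L, length.out = k)
}
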
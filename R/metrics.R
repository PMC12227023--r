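# Per-movement metrics: peak velocity indexes the preprogrammed (open-loop
# pulse) component of accommodation, final amplitude the feedback
# (closed-loop) component. Plus movement validity flags, the 2-SD
# intra-participant outlier rule, and participant-level summaries.

#' Peak velocity of a movement
#'
#' The maximum observed rate of change of the response: the maximum of the
#' velocity trace for focus (far-to-near) movements and the minimum for
#' defocus, reported signed (focus positive). Use `magnitude = TRUE` for
#' the absolute value used in group comparisons.
#'
#' @param trace A `movement_trace` with velocity computed (as produced by
#'   [segment_movements()]).
#' @param magnitude Return `|PV|` instead of the signed value.
#' @return Peak velocity in D/s.
#' @export
peak_velocity <- function(trace, magnitude = FALSE) {
  stopifnot(inherits(trace, "movement_trace"))
  v <- trace$velocity %||% compute_velocity(trace$refraction, trace$fs)
  v <- v[is.finite(v)]
  if (!length(v)) stopf("velocity trace has no finite samples")
  pv <- if (trace$direction == "focus") max(v) else min(v)
  if (magnitude) abs(pv) else pv
}

#' Final amplitude of a movement
#'
#' The mean of the last half-second of the baseline-aligned position trace
#' — 25 samples at 50 Hz. Measures how completely the feedback component
#' closed on the stimulated demand; `FA / demand` is the response gain.
#'
#' @param trace A `movement_trace` (length >= `window_samples`).
#' @param window_samples Averaging window length in samples (default 25,
#'   i.e. 0.5 s at 50 Hz).
#' @return Final amplitude in D (signed: negative for defocus).
#' @export
final_amplitude <- function(trace, window_samples = 25L) {
  stopifnot(inherits(trace, "movement_trace"))
  n <- length(trace$refraction)
  if (n < window_samples)
    stopf("trace has %d samples; need at least %d for the FA window", n,
          window_samples)
  mean(trace$refraction[(n - window_samples + 1L):n])
}

#' Movement validity thresholds
#'
#' Defaults operationalising the "non-response, noise, or signal recording
#' artifact" exclusions: a movement is `NON_RESPONSE` when `|FA|` is below
#' `min_fa` (default 0.2 D on a 1.5 D step), `NOISE` when any velocity
#' sample exceeds `max_velocity` (default 25 D/s) in magnitude, and
#' `ARTIFACT` when more than `max_interp_frac` of its window was
#' gap-interpolated.
#'
#' @param min_fa Minimum `|FA|` (D) for a response to count.
#' @param max_velocity Maximum plausible `|velocity|` (D/s).
#' @param max_interp_frac Maximum tolerated gap-interpolated fraction.
#' @return Named list of thresholds.
#' @export
validity_thresholds <- function(min_fa = 0.2, max_velocity = 25,
                                max_interp_frac = 0.10) {
  list(min_fa = min_fa, max_velocity = max_velocity,
       max_interp_frac = max_interp_frac)
}

#' Classify a movement as valid or flag why not
#'
#' @param trace A `movement_trace`.
#' @param fa,pv Optionally precomputed final amplitude and peak velocity.
#' @param thresholds A [validity_thresholds()] list.
#' @return `"valid"`, `"NON_RESPONSE"`, `"NOISE"` or `"ARTIFACT"` (the
#'   first triggered flag, checked in the order artifact, noise,
#'   non-response).
#' @export
movement_validity <- function(trace, fa = NULL, pv = NULL,
                              thresholds = validity_thresholds()) {
  stopifnot(inherits(trace, "movement_trace"))
  v <- trace$velocity %||% compute_velocity(trace$refraction, trace$fs)
  fa <- fa %||% final_amplitude(trace)
  if ((trace$interp_frac %||% 0) > thresholds$max_interp_frac) return("ARTIFACT")
  if (max(abs(v)) > thresholds$max_velocity) return("NOISE")
  if (abs(fa) < thresholds$min_fa) return("NON_RESPONSE")
  "valid"
}

#' Per-movement metric table for a set of traces
#'
#' @param traces List of `movement_trace` objects (one recording's worth or
#'   any mix).
#' @param thresholds [validity_thresholds()] used for the validity flags.
#' @return Tidy tibble with one row per movement: `participant_id`, `cue`,
#'   `direction`, `movement`, `pv` (signed, D/s), `fa` (signed, D),
#'   `demand_step`, `interp_frac`, `validity`, `valid`.
#' @export
movement_metrics <- function(traces, thresholds = validity_thresholds()) {
  stopifnot(length(traces) > 0)
  fa <- vapply(traces, final_amplitude, numeric(1))
  pv <- vapply(traces, peak_velocity, numeric(1))
  flag <- vapply(seq_along(traces), function(i)
    movement_validity(traces[[i]], fa = fa[i], pv = pv[i],
                      thresholds = thresholds), character(1))
  tibble::tibble(
    participant_id = vapply(traces, `[[`, character(1), "participant_id"),
    cue = vapply(traces, `[[`, character(1), "cue"),
    direction = vapply(traces, `[[`, character(1), "direction"),
    movement = seq_along(traces),
    pv = pv, fa = fa,
    demand_step = vapply(traces, `[[`, numeric(1), "demand_step"),
    interp_frac = vapply(traces, `[[`, numeric(1), "interp_frac"),
    validity = flag, valid = flag == "valid"
  )
}

#' Flag intra-participant movement outliers by the 2-SD rule
#'
#' Single-pass rule applied within one participant x cue x direction cell:
#' a movement is an outlier iff its metric lies 2 or more sample standard
#' deviations from the cell mean, with mean and sd computed once over all
#' supplied values. When all values are equal (sd 0) nothing is flagged;
#' with fewer than 3 values the rule is skipped with a warning.
#'
#' @param x Numeric metric values (one participant-cell's movements).
#' @param n_sd Threshold in standard deviations (default 2).
#' @return Logical vector, `TRUE` = outlier.
#' @export
flag_intra_outliers <- function(x, n_sd = 2) {
  if (length(x) < 3L) {
    warning("fewer than 3 movements; intra-participant outlier rule skipped",
            call. = FALSE)
    return(rep(FALSE, length(x)))
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - mean(x)) >= n_sd * s
}

#' Remove intra-participant outlier movements from a metric table
#'
#' Applies [flag_intra_outliers()] independently per metric (`pv`, `fa`)
#' within each participant x cue x direction cell of a [movement_metrics()]
#' table, using only movements marked valid. Adds logical columns
#' `outlier_pv` and `outlier_fa`; invalid movements are never flagged (they
#' are excluded earlier).
#'
#' @param metrics A [movement_metrics()] tibble.
#' @param n_sd Threshold in standard deviations.
#' @return The table with `outlier_pv` / `outlier_fa` columns added.
#' @export
remove_intra_outliers <- function(metrics, n_sd = 2) {
  metrics$outlier_pv <- FALSE
  metrics$outlier_fa <- FALSE
  cells <- interaction(metrics$participant_id, metrics$cue, metrics$direction,
                       drop = TRUE)
  for (cell in levels(cells)) {
    idx <- which(cells == cell & metrics$valid)
    if (!length(idx)) next
    metrics$outlier_pv[idx] <- flag_intra_outliers(metrics$pv[idx], n_sd)
    metrics$outlier_fa[idx] <- flag_intra_outliers(metrics$fa[idx], n_sd)
  }
  metrics
}

#' Participant-level summaries per cue and direction
#'
#' Means and sds of the surviving movements (valid, non-outlier; the 2-SD
#' rule is applied per metric, so a movement may count for `fa` but not
#' `pv`). Gain is `mean_fa / demand_step`, computed on magnitudes. Cells
#' with a single surviving movement report sd 0 with `sd_defined = FALSE`;
#' cells with zero survivors are dropped.
#'
#' @param metrics A [remove_intra_outliers()] table (the outlier columns
#'   are added if absent).
#' @param demand_step Stimulated demand step (D) used for gain; defaults to
#'   the per-movement `demand_step` column.
#' @return Tibble with one row per participant x cue x direction:
#'   `n_used_pv`, `n_used_fa`, `mean_pv`, `sd_pv`, `mean_fa`, `sd_fa`,
#'   `gain`, `sd_defined`.
#' @export
summarize_participants <- function(metrics, demand_step = NULL) {
  if (!"outlier_pv" %in% names(metrics))
    metrics <- remove_intra_outliers(metrics)
  key <- interaction(metrics$participant_id, metrics$cue, metrics$direction,
                     drop = TRUE, sep = "\r")
  cells <- levels(key)
  parts <- strsplit(cells, "\r", fixed = TRUE)
  idx_by_cell <- split(seq_len(nrow(metrics)), key)
  stat <- vapply(idx_by_cell, function(idx) {
    sel <- idx[metrics$valid[idx]]
    pv <- abs(metrics$pv[sel[!metrics$outlier_pv[sel]]])
    fa <- abs(metrics$fa[sel[!metrics$outlier_fa[sel]]])
    dstep <- if (length(sel)) metrics$demand_step[sel][1] else NA_real_
    c(n_pv = length(pv), n_fa = length(fa),
      mean_pv = if (length(pv)) mean(pv) else NA_real_,
      sd_pv = if (length(pv) > 1L) sd(pv) else 0,
      mean_fa = if (length(fa)) mean(fa) else NA_real_,
      sd_fa = if (length(fa) > 1L) sd(fa) else 0,
      dstep = demand_step %||% dstep)
  }, numeric(7))
  keep <- stat["n_pv", ] > 0 | stat["n_fa", ] > 0
  if (!any(keep)) stopf("no cell has any surviving movement")
  stat <- stat[, keep, drop = FALSE]
  parts <- parts[keep]
  tibble::tibble(
    participant_id = vapply(parts, `[`, character(1), 1L),
    cue = vapply(parts, `[`, character(1), 2L),
    direction = vapply(parts, `[`, character(1), 3L),
    n_used_pv = as.integer(unname(stat["n_pv", ])),
    n_used_fa = as.integer(unname(stat["n_fa", ])),
    mean_pv = unname(stat["mean_pv", ]), sd_pv = unname(stat["sd_pv", ]),
    mean_fa = unname(stat["mean_fa", ]), sd_fa = unname(stat["sd_fa", ]),
    gain = unname(stat["mean_fa", ] / stat["dstep", ]),
    sd_defined = unname(stat["n_pv", ] > 1 & stat["n_fa", ] > 1)
  )
}

#' Convergence-accommodation to convergence (CA/C) ratio
#'
#' The accommodative final amplitude driven purely by disparity vergence
#' (the D(-bp) condition) divided by the vergence final amplitude, in
#' diopters per prism diopter.
#'
#' @param accom_fa Accommodative final amplitude (D).
#' @param vergence_fa Vergence final amplitude (prism diopters); must be
#'   nonzero.
#' @return CA/C ratio in D per prism diopter.
#' @examples
#' ca_c_ratio(1.0, 2.0)   # 0.5
#' @export
ca_c_ratio <- function(accom_fa, vergence_fa) {
  if (!is.numeric(accom_fa) || !is.numeric(vergence_fa))
    stopf("inputs must be numeric")
  if (any(vergence_fa == 0)) stopf("vergence final amplitude must be nonzero")
  accom_fa / vergence_fa
}
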
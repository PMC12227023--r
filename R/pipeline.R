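# End-to-end orchestration: QC -> preprocess -> segment -> metrics ->
# outlier removal -> group inference, with tidy intermediate tables, a
# disposition manifest, and the report artifacts (peak-velocity-aligned
# group averages, violin summary statistics, pairwise p-value matrix).

#' Run QC, preprocessing and metric extraction over a set of recordings
#'
#' @param recs Named list of `accom_recording` objects.
#' @param validity [validity_thresholds()] for movement flags.
#' @param qc_args List of overrides for [apply_rejection()] thresholds.
#' @param n_sd Intra-participant outlier threshold (standard deviations).
#' @param keep_traces Keep the segmented `movement_trace` objects (grouped
#'   by cue) for group-average reporting.
#' @return List with `qc` (per-file tibble), `movements` (per-movement
#'   metric tibble with outlier flags), `summaries`
#'   ([summarize_participants()] tibble), `traces_by_cue` (if requested)
#'   and `counts` (files and movement dispositions).
#' @export
analyze_recordings <- function(recs, validity = validity_thresholds(),
                               qc_args = list(), n_sd = 2,
                               keep_traces = FALSE) {
  stopifnot(length(recs) > 0)
  qc_rows <- vector("list", length(recs))
  mov_rows <- vector("list", length(recs))
  traces_by_cue <- list()
  n_dropped_windows <- 0L
  for (i in seq_along(recs)) {
    rec <- substitute_eye(recs[[i]])
    qc <- do.call(apply_rejection, c(list(rec), qc_args))
    qc_rows[[i]] <- list(
      participant_id = qc$participant_id, cue = qc$cue,
      n_samples = qc$n_samples, missing_fraction = qc$missing_fraction,
      longest_missing_run = qc$longest_missing_run, n_valid = qc$n_valid,
      completeness = qc$completeness, accepted = qc$accepted,
      reasons = paste(qc$reasons, collapse = ";")
    )
    if (!qc$accepted) next
    rec <- preprocess_recording(rec)
    traces <- withCallingHandlers(
      segment_movements(rec),
      warning = function(w) invokeRestart("muffleWarning")
    )
    n_dropped_windows <- n_dropped_windows + attr(traces, "n_dropped")
    if (!length(traces)) next
    mov_rows[[i]] <- movement_metrics(traces, thresholds = validity)
    if (keep_traces)
      traces_by_cue[[rec$cue]] <- c(traces_by_cue[[rec$cue]], traces)
  }
  fld <- function(name, mode) vapply(qc_rows, `[[`, vector(mode, 1L), name)
  qc_tbl <- tibble::tibble(
    participant_id = fld("participant_id", "character"),
    cue = fld("cue", "character"),
    n_samples = fld("n_samples", "integer"),
    missing_fraction = fld("missing_fraction", "numeric"),
    longest_missing_run = as.integer(fld("longest_missing_run", "numeric")),
    n_valid = as.integer(fld("n_valid", "numeric")),
    completeness = fld("completeness", "numeric"),
    accepted = fld("accepted", "logical"),
    reasons = fld("reasons", "character")
  )
  movements <- do.call(rbind, mov_rows[!vapply(mov_rows, is.null, logical(1))])
  if (is.null(movements) || !nrow(movements))
    stopf("no recording survived quality control")
  movements <- remove_intra_outliers(movements, n_sd = n_sd)
  summaries <- summarize_participants(movements)
  counts <- list(
    files_in = length(recs),
    files_rejected = sum(!qc_tbl$accepted),
    windows_dropped = n_dropped_windows,
    movements_in = nrow(movements),
    movements_invalid = sum(!movements$valid),
    movements_outlier_pv = sum(movements$outlier_pv),
    movements_outlier_fa = sum(movements$outlier_fa),
    movements_used_pv = sum(movements$valid & !movements$outlier_pv),
    movements_used_fa = sum(movements$valid & !movements$outlier_fa)
  )
  out <- list(qc = qc_tbl, movements = movements, summaries = summaries,
              counts = counts)
  if (keep_traces) out$traces_by_cue <- traces_by_cue
  out
}

#' Peak-velocity-aligned group-average curves per cue
#'
#' Applies [align_at_peak_velocity()] within each cue and direction
#' stratum (focus and defocus responses are averaged separately) and
#' stacks the results into one tidy table, the numerical form of the
#' group-level average position/velocity figure. Cues with no traces are
#' omitted with a warning.
#'
#' @param traces_by_cue Named list: cue code -> list of `movement_trace`.
#' @return Tibble with `cue`, `direction`, `rel_t`, `mean_pos`, `sd_pos`,
#'   `mean_vel`, `sd_vel`, `n`.
#' @export
group_average_report <- function(traces_by_cue) {
  stopifnot(is.list(traces_by_cue), length(traces_by_cue) > 0)
  empty <- lengths(traces_by_cue) == 0L
  if (any(empty)) {
    warning(sprintf("cue(s) with zero traces omitted: %s",
                    paste(names(traces_by_cue)[empty], collapse = ", ")),
            call. = FALSE)
    traces_by_cue <- traces_by_cue[!empty]
  }
  rows <- list()
  for (cue in names(traces_by_cue)) {
    traces <- traces_by_cue[[cue]]
    dirs <- vapply(traces, `[[`, character(1), "direction")
    for (d in unique(dirs)) {
      avg <- align_at_peak_velocity(traces[dirs == d])
      rows[[paste(cue, d)]] <- tibble::tibble(cue = cue, direction = d, avg)
    }
  }
  do.call(rbind, rows)
}

#' Violin-plot summary statistics per cue
#'
#' The numbers behind a violin/box display: median, mean, quartiles (linear
#' interpolation of order statistics), 1.5 x IQR whisker bounds and the
#' count of values flagged outside them.
#'
#' @param values_by_cue Named list: cue code -> numeric metric values
#'   (>= 4 per cue for outlier flags).
#' @return Tibble with `cue`, `n`, `median`, `mean`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
violin_summary <- function(values_by_cue) {
  stopifnot(is.list(values_by_cue), length(values_by_cue) > 0)
  rows <- lapply(names(values_by_cue), function(cue) {
    x <- values_by_cue[[cue]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    flags <- if (length(x) >= 4L) iqr_outliers(x) else rep(FALSE, length(x))
    tibble::tibble(
      cue = cue, n = length(x), median = q[2], mean = mean(x),
      q1 = q[1], q3 = q[3], iqr = iqr,
      whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
      n_outliers = sum(flags)
    )
  })
  do.call(rbind, rows)
}

# Wide pairwise p-value matrix: one row per cue pair, one column per
# metric x direction stratum.
pairwise_table <- function(inferences) {
  base <- NULL
  for (inf in inferences) {
    col <- sprintf("%s_%s", inf$metric, inf$direction)
    pw <- inf$pairwise
    if (is.null(pw)) next
    tbl <- tibble::tibble(group1 = pw$group1, group2 = pw$group2)
    tbl[[col]] <- pw$p
    base <- if (is.null(base)) tbl else merge(base, tbl,
                                              by = c("group1", "group2"),
                                              all = TRUE, sort = FALSE)
  }
  if (is.null(base)) return(NULL)
  tibble::as_tibble(base)
}

#' Run the full analysis pipeline
#'
#' One reproducible run of synth/ingest -> QC -> preprocess -> metrics ->
#' group stats. Input is either a [sim_config()] (a synthetic cohort is
#' generated) or a directory of recording CSVs — exactly one of the two.
#' When `out_dir` is given, every intermediate table, the group-average
#' and violin reports, the pairwise p-value matrix and a JSON manifest are
#' written there; reruns with the same config produce identical outputs.
#'
#' @param config A [sim_config()], or `NULL` when reading from disk.
#' @param input_dir Directory of recording CSVs, or `NULL`.
#' @param out_dir Optional output directory.
#' @param alpha Significance level for the main-effect gate.
#' @param validity [validity_thresholds()].
#' @param qc_args Overrides for [apply_rejection()].
#' @param n_sd Intra-participant outlier threshold.
#' @return List with `qc`, `movements`, `summaries`, `counts`,
#'   `inferences` (one `group_inference` per metric x direction),
#'   `pairwise_table`, `group_average`, `violin_fa`, `violin_pv`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, out_dir = NULL,
                         alpha = 0.05, validity = validity_thresholds(),
                         qc_args = list(), n_sd = 2) {
  if (is.null(config) == is.null(input_dir))
    stopf("supply exactly one input source: `config` or `input_dir`")
  recs <- if (!is.null(config)) {
    stopifnot(inherits(config, "sim_config"))
    simulate_cohort(config)
  } else {
    read_cohort(input_dir)
  }
  res <- analyze_recordings(recs, validity = validity, qc_args = qc_args,
                            n_sd = n_sd, keep_traces = TRUE)

  strata <- expand.grid(metric = c("pv", "fa"),
                        direction = c("focus", "defocus"),
                        stringsAsFactors = FALSE)
  inferences <- lapply(seq_len(nrow(strata)), function(i)
    main_effect_workflow(res$summaries, strata$metric[i], strata$direction[i],
                         alpha = alpha))
  names(inferences) <- sprintf("%s_%s", strata$metric, strata$direction)

  group_avg <- group_average_report(res$traces_by_cue)
  focus_sum <- res$summaries[res$summaries$direction == "focus", ]
  violin_fa <- violin_summary(split(focus_sum$mean_fa, focus_sum$cue))
  violin_pv <- violin_summary(split(focus_sum$mean_pv, focus_sum$cue))
  pw_tbl <- pairwise_table(inferences)

  manifest <- list(
    package_version = as.character(utils::packageVersion("accomstep")),
    input = if (!is.null(config)) "synthetic" else input_dir,
    seed = if (!is.null(config)) config$seed else NA_integer_,
    alpha = alpha,
    counts = res$counts,
    kw = lapply(inferences, function(inf)
      list(H = inf$kw$H, df = inf$kw$df, p = inf$kw$p,
           n_pairwise = if (is.null(inf$pairwise)) 0L else nrow(inf$pairwise),
           iqr_outliers_removed = inf$n_outliers_removed))
  )

  out <- list(qc = res$qc, movements = res$movements,
              summaries = res$summaries, counts = res$counts,
              inferences = inferences, pairwise_table = pw_tbl,
              group_average = group_avg, violin_fa = violin_fa,
              violin_pv = violin_pv, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(out$qc, "qc.csv")
  wcsv(out$movements, "movements.csv")
  wcsv(out$summaries, "participant_summaries.csv")
  wcsv(out$group_average, "group_average.csv")
  wcsv(out$violin_fa, "violin_fa.csv")
  wcsv(out$violin_pv, "violin_pv.csv")
  if (!is.null(out$pairwise_table)) wcsv(out$pairwise_table, "dscf_pairwise.csv")
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  assumptions <- lapply(out$inferences, function(inf) list(
    levene_W = inf$assumptions$levene$W, levene_p = inf$assumptions$levene$p,
    shapiro_p = lapply(inf$assumptions$shapiro, `[[`, "p"),
    parametric_ok = inf$assumptions$parametric_ok))
  jsonlite::write_json(assumptions, file.path(out_dir, "assumptions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
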
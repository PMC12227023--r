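test_that("recording CSV dialect round-trips losslessly", {
  cfg <- sim_config(n_participants = 1, seed = 8)
  rec <- simulate_cohort(cfg, cues = "BD-p")[[1]]
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(is.na(back$od), is.na(rec$od))
  expect_identical(is.na(back$os), is.na(rec$os))
  expect_equal(back$od, rec$od, tolerance = 1e-9)
  expect_equal(back$os, rec$os, tolerance = 1e-9)
  expect_equal(back$participant_id, rec$participant_id)
  expect_equal(back$cue, rec$cue)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$calibration_factor, rec$calibration_factor)
  # event log preserved in order
  expect_equal(back$events$movement_index, rec$events$movement_index)
  expect_equal(back$events$direction, rec$events$direction)
  expect_equal(back$events$onset_s, rec$events$onset_s, tolerance = 1e-9)
})

test_that("missing samples serialize as empty fields and re-read as missing", {
  rec <- make_masked_recording(300, missing_idx = c(5, 6, 100))
  path <- file.path(withr::local_tempdir(), "m.csv")
  write_recording(rec, path)
  lines <- readLines(path)
  expect_match(lines[5 + 5], ",,$")  # header(4) + colnames(1) + row 5
  back <- read_recording(path)
  expect_identical(which(is.na(back$od)), c(5L, 6L, 100L))
})

test_that("malformed recordings raise errors naming the problem line", {
  dir <- withr::local_tempdir()
  rec <- make_masked_recording(100)
  path <- file.path(dir, "x.csv")
  write_recording(rec, path)
  lines <- readLines(path)
  lines[20] <- "0.28,1.5"  # truncated row (row 15 of data -> file line 20)
  writeLines(lines, path)
  expect_error(read_recording(path), "line 20")
  writeLines(c("# fs_hz 50", lines[-1]), path)
  expect_error(read_recording(path), "malformed header")
  expect_error(read_recording(file.path(dir, "absent.csv")), "not found")
})

test_that("eye substitution copies the valid eye and counts repairs", {
  od <- c(1, NA, 3, NA, 5)
  os <- c(10, 20, NA, NA, 50)
  rec <- make_recording(od, os)
  out <- substitute_eye(rec)
  expect_equal(out$od, c(1, 20, 3, NA, 5))
  expect_equal(out$os, c(10, 20, 3, NA, 50))
  expect_equal(out$substitutions, c(od = 1L, os = 1L))
  # untouched where the target eye is valid
  expect_equal(out$od[c(1, 3, 5)], od[c(1, 3, 5)])
  # identity when nothing is missing
  clean <- make_recording(c(1, 2, 3))
  expect_identical(substitute_eye(clean)$od, clean$od)
})

test_that("missing fraction and longest run are computed on the combined mask", {
  rec <- make_masked_recording(250, missing_idx = 1:50)
  expect_equal(missing_fraction(rec), 0.2)
  expect_equal(missing_fraction(make_masked_recording(100)), 0)
  expect_equal(missing_fraction(rep(TRUE, 10)), 1)
  mask <- rep(FALSE, 400)
  mask[11:20] <- TRUE; mask[51:280] <- TRUE; mask[301:305] <- TRUE
  expect_equal(longest_missing_run(mask), 230L)
  expect_equal(longest_missing_run(rep(FALSE, 50)), 0L)
})

test_that("longest run agrees with a brute-force scan on random masks", {
  brute <- function(mask) {
    best <- 0L
    for (i in seq_along(mask)) for (j in i:length(mask)) {
      if (all(mask[i:j])) best <- max(best, j - i + 1L) else break
    }
    best
  }
  withr::with_seed(42, {
    for (rep in 1:25) {
      mask <- runif(sample(1:30, 1)) < 0.4
      expect_equal(longest_missing_run(mask), brute(mask))
    }
  })
})

test_that("rejection rules fire at their inclusive thresholds", {
  # 8000 samples, 24.9% missing, spread gaps -> accepted
  ok <- make_masked_recording(8000, spread_missing(8000, 1992))
  expect_true(apply_rejection(ok)$accepted)
  # exactly 25% missing -> rejected (">= 25%")
  r1 <- apply_rejection(make_masked_recording(8000, spread_missing(8000, 2000)))
  expect_false(r1$accepted)
  expect_equal(r1$reasons, "DATA_LOSS_25PCT")
  # exactly one 225-sample gap -> rejected ("225 or greater")
  r2 <- apply_rejection(make_masked_recording(8000, 1000:1224))
  expect_false(r2$accepted)
  expect_true("GAP_225" %in% r2$reasons)
  # 224-sample gap alone -> accepted
  expect_true(apply_rejection(make_masked_recording(8000, 1000:1223))$accepted)
  # 700 valid samples -> rejected as too short
  r3 <- apply_rejection(make_masked_recording(760, spread_missing(760, 60)),
                        max_missing_frac = 0.5)
  expect_equal(r3$n_valid, 700L)
  expect_true("TOO_SHORT_750" %in% r3$reasons)
  # multiple reasons co-occur, deterministically ordered
  r4 <- apply_rejection(make_masked_recording(800, 1:400))
  expect_setequal(r4$reasons, c("DATA_LOSS_25PCT", "TOO_SHORT_750", "GAP_225"))
  expect_identical(r4$reasons, sort(r4$reasons))
  expect_false(r4$accepted)
})

test_that("substitution happens before rejection by default", {
  # one eye fully missing, other intact: combined signal is complete
  n <- 1000
  rec <- make_recording(od = rep(NA_real_, n), os = rep(1.5, n))
  expect_true(apply_rejection(rec)$accepted)
  expect_false(apply_rejection(rec, presubstitution = TRUE)$accepted)
})

test_that("rejection is monotone in added missingness", {
  withr::with_seed(7, {
    for (i in 1:10) {
      base_idx <- sample(2000, 600)
      rec <- make_masked_recording(2000, base_idx)
      qc <- apply_rejection(rec)
      more <- make_masked_recording(2000, union(base_idx, sample(2000, 400)))
      qc2 <- apply_rejection(more)
      if (!qc$accepted) expect_false(qc2$accepted)
    }
  })
})

test_that("short gaps interpolate linearly with edge fill", {
  od <- c(1.0, NA, NA, 1.3, 2.0)
  rec <- make_recording(od)
  out <- interpolate_short_gaps(rec)
  expect_equal(out$od, c(1.0, 1.1, 1.2, 1.3, 2.0))
  expect_identical(out$interp_mask, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # leading gap takes the nearest valid value
  lead <- interpolate_short_gaps(make_recording(c(NA, NA, NA, 2.0, 2.5)))
  expect_equal(lead$od[1:3], rep(2.0, 3))
  # no gaps: identity
  clean <- make_recording(c(1, 2, 3))
  expect_identical(interpolate_short_gaps(clean)$od, clean$od)
  # all missing: error
  expect_error(interpolate_short_gaps(make_recording(rep(NA_real_, 10))),
               "no valid samples")
})
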
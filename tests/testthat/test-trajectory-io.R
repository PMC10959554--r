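short_trial <- function() {
  generate_trial(gait_scenario(90, approach_length = 2, exit_length = 1))
}

test_that("TRC files round-trip bit-identically", {
  rec <- short_trial()$recording
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  rec2 <- read_trc(path)
  expect_identical(rec2$markers, rec$markers)
  expect_identical(rec2$sampling_rate, rec$sampling_rate)
  hdr <- strsplit(readLines(path, n = 3)[3], "\t")[[1]]
  expect_equal(as.numeric(hdr[1]), 120)
})

test_that("TRC units in millimeters are converted to meters", {
  path <- withr::local_tempfile(fileext = ".trc")
  writeLines(c(
    "PathFileType\t4\t(X/Y/Z)\tx.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    "120\t120\t2\t1\tmm\t120\t1\t2",
    "Frame#\tTime\tM1\t\t",
    "\t\tX1\tY1\tZ1",
    "",
    "1\t0.000000\t1000\t0\t0",
    "2\t0.008333\t1000\t0\t0"), path)
  rec <- read_trc(path, required = FALSE)
  expect_equal(unname(rec$markers[[1]][1, 1]), 1.0)
})

test_that("damaged TRC files raise parse errors instead of silent truncation", {
  rec <- short_trial()$recording
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  lines <- readLines(path)
  writeLines(lines[1:4], path)
  expect_error(read_trc(path), "TRC|valid")
  writeLines(lines[-length(lines)], path)
  expect_error(read_trc(path), "frame-count mismatch")
  # drop fields from one data row
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  lines2 <- readLines(path)
  lines2[7] <- paste(strsplit(lines2[7], "\t")[[1]][1:10], collapse = "\t")
  writeLines(lines2, path)
  expect_error(read_trc(path), "truncated|fields")
})

test_that("a missing required marker is reported by name", {
  rec <- short_trial()$recording
  rec$markers$LPSI <- NULL
  rec <- trial_recording(rec$markers, rec$sampling_rate)
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(rec, path)
  expect_error(read_trc(path), "LPSI")
})

test_that("CSV trajectories round-trip and match TRC downstream", {
  trial <- short_trial()
  rec <- trial$recording
  pcsv <- withr::local_tempfile(fileext = ".csv")
  ptrc <- withr::local_tempfile(fileext = ".trc")
  write_csv_trajectories(rec, pcsv)
  write_trc(rec, ptrc)
  rec_csv <- read_csv_trajectories(pcsv)
  rec_trc <- read_trc(ptrc)
  expect_identical(rec_csv$markers, rec$markers)
  a <- suppressWarnings(analyze_trial(rec_csv))
  b <- suppressWarnings(analyze_trial(rec_trc))
  expect_identical(a$parameters, b$parameters)
})

test_that("empty recordings cannot be constructed or written", {
  expect_error(trial_recording(list(), 120), "named list|no markers")
  expect_error(trial_recording(list(A = matrix(numeric(0), 0, 3)), 120),
               "empty")
})

test_that("ground-truth sidecars round-trip through JSON", {
  trial <- short_trial()
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(trial$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$events$frame, trial$truth$events$frame)
  expect_equal(back$nominal$cadence, trial$truth$nominal$cadence)
  expect_equal(back$scenario$step_interval, trial$truth$scenario$step_interval)
})

test_that("results tables keep the canonical parameter ordering", {
  pars <- sample(PARAMETER_ORDER)
  long <- expand.grid(parameter = pars, speed = c("normal", "slow"),
                      amplitude = 90, stringsAsFactors = FALSE)
  long$mean <- seq_len(nrow(long))
  long$ci_low <- long$mean - 1
  long$ci_high <- long$mean + 1
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- write_results_table(long, path)
  expect_identical(wide$parameter, PARAMETER_ORDER)
  expect_identical(read.csv(path)$parameter, PARAMETER_ORDER)
})
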
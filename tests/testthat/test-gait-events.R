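test_that("the pelvis frame recovers the facing direction", {
  rec <- make_standing_recording(duration = 1)
  fr <- pelvis_frame(rec)
  expect_equal(fr$forward[1, ], c(1, 0, 0), tolerance = 1e-12)
  rec90 <- make_standing_recording(duration = 1,
                                   yaw_fun = function(t) rep(90, length(t)))
  fr90 <- pelvis_frame(rec90)
  expect_equal(fr90$forward[1, ], c(0, 1, 0), tolerance = 1e-12)
  expect_true(all(abs(rowSums(fr$forward * fr$lateral)) < 1e-12))
})

test_that("degenerate pelvis geometry is rejected", {
  rec <- make_standing_recording(duration = 0.5)
  rec$markers$RASI <- rec$markers$LASI
  expect_error(pelvis_frame(rec), "degenerate pelvis")
})

test_that("the pelvis forward axis tracks the path tangent on the straights", {
  tr <- generate_trial(quick_scenario(90, turn_direction = "left"))
  fr <- pelvis_frame(tr$recording)
  n <- tr$recording$n_frames
  expect_equal(fr$forward[5, 1:2], c(1, 0), tolerance = 1e-9)
  expect_equal(fr$forward[n - 5, 1:2], c(0, 1), tolerance = 1e-9)
})

test_that("standing still produces no gait events", {
  rec <- make_standing_recording(duration = 4)
  expect_equal(nrow(detect_heel_strikes(rec)), 0)
  expect_equal(nrow(detect_toe_offs(rec)), 0)
})

test_that("noise-free events are recovered exactly; 1 mm noise costs at most 2 frames", {
  tr <- generate_trial(quick_scenario(90, step_interval = 0.531))
  m <- event_match(suppressMessages(gait_events(tr$recording)), tr$truth)
  expect_true(m$count_ok)
  expect_lte(m$worst, 1)

  trn <- generate_trial(quick_scenario(90, step_interval = 0.531,
                                       noise_sd = 0.001, seed = 9L))
  mn <- event_match(suppressMessages(gait_events(trn$recording)), trn$truth)
  expect_true(mn$count_ok)
  expect_lte(mn$worst, 2)
})

test_that("a sinusoidal toe excursion yields toe-offs spaced one period apart", {
  rate <- 120
  period <- 1.2
  t <- seq(0, 8, by = 1 / rate)
  base <- make_standing_recording(duration = 8)
  sway <- 0.3 * sin(2 * pi * t / period)
  for (m in c("L_TOE", "L_HEEL")) base$markers[[m]][, 1] <-
      base$markers[[m]][, 1] + sway
  for (m in c("R_TOE", "R_HEEL")) base$markers[[m]][, 1] <-
      base$markers[[m]][, 1] + 0.3 * cos(2 * pi * t / period)
  to <- detect_toe_offs(base)
  gaps <- diff(to$time[to$side == "left"])
  expect_true(all(abs(gaps - period) <= 2 / rate))
})

test_that("merged events alternate per side and duplicates are dropped loudly", {
  hs <- data.frame(time = c(0.5, 1.5), frame = c(60L, 180L),
                   side = "left", type = "heel_strike",
                   stringsAsFactors = FALSE)
  to <- data.frame(time = 1.0, frame = 120L, side = "left", type = "toe_off",
                   stringsAsFactors = FALSE)
  ev <- merge_and_validate(hs, to)
  expect_identical(ev$type, c("heel_strike", "toe_off", "heel_strike"))
  expect_equal(nrow(attr(ev, "dropped")), 0)

  hs_dup <- rbind(hs, data.frame(time = 0.6, frame = 72L, side = "left",
                                 type = "heel_strike", stringsAsFactors = FALSE))
  expect_message(ev2 <- merge_and_validate(hs_dup, to), "dropped 1")
  expect_equal(nrow(attr(ev2, "dropped")), 1)
  expect_equal(attr(ev2, "dropped")$frame, 72L)

  expect_error(merge_and_validate(hs[1, ], to), "insufficient gait")
})

test_that("event detection is invariant to lab-frame rotation and translation", {
  tr <- generate_trial(quick_scenario(180))
  ev1 <- suppressMessages(gait_events(tr$recording))
  rec2 <- transform_recording(tr$recording, angle_deg = 37, offset = c(5, -3, 0))
  ev2 <- suppressMessages(gait_events(rec2))
  expect_identical(ev1$frame, ev2$frame)
  expect_identical(ev1$side, ev2$side)
  expect_identical(ev1$type, ev2$type)
})

test_that("detected event counts equal the ground-truth counts", {
  tr <- generate_trial(quick_scenario(360, step_interval = 0.55))
  ev <- suppressMessages(gait_events(tr$recording))
  expect_equal(nrow(ev), nrow(tr$truth$events))
})
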
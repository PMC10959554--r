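test_that("a straight walk has zero pelvis yaw and collinear footfalls", {
  sc <- quick_scenario(0, step_width_offset = 0)
  tr <- generate_trial(sc)
  yaw <- pelvis_yaw_rate(tr$recording)
  expect_lt(max(abs(yaw$rate)), 1e-6)
  expect_lt(max(abs(tr$truth$footfalls$y)), 1e-9)
})

test_that("ground-truth heel-strike intervals equal the configured step interval", {
  sc <- quick_scenario(90, step_interval = 0.531)
  tr <- generate_trial(sc)
  hs <- tr$truth$events
  hs <- hs[hs$type == "heel_strike", ]
  gaps <- diff(sort(hs$time))
  expect_true(all(abs(gaps - 0.531) <= 1 / sc$sampling_rate + 1e-12))
})

test_that("consecutive same-leg contacts are exactly one stride length apart", {
  for (amp in c(90, 180, 360)) {
    sc <- quick_scenario(amp, step_length = 0.57)
    ff <- generate_trial(sc)$truth$footfalls
    for (s in c("left", "right")) {
      f <- ff[ff$side == s, ]
      d <- sqrt(diff(f$x)^2 + diff(f$y)^2)
      expect_lt(max(abs(d - 2 * sc$step_length)), 1e-9)
    }
  }
})

test_that("total pelvis yaw change equals the turn amplitude within 1 degree", {
  for (amp in c(90, 180, 360)) {
    for (dir in c("left", "right")) {
      tr <- generate_trial(quick_scenario(amp, turn_direction = dir))
      fr <- pelvis_frame(tr$recording)
      yaw <- atan2(fr$forward[, 2], fr$forward[, 1])
      yaw <- yaw - c(0, cumsum(round(diff(yaw) / (2 * pi)))) * 2 * pi
      span <- (yaw[length(yaw)] - yaw[1]) * 180 / pi
      expect_equal(span, if (dir == "left") amp else -amp, tolerance = 1 / amp)
    }
  }
})

test_that("the heel marker reproduces ground-truth footfalls at contact", {
  tr <- generate_trial(quick_scenario(90))
  ff <- tr$truth$footfalls
  ff <- ff[ff$frame >= 0 & ff$frame < tr$recording$n_frames - 5, ]
  for (i in seq_len(nrow(ff))) {
    heel <- marker(tr$recording,
                   if (ff$side[i] == "left") "L_HEEL" else "R_HEEL")
    expect_lt(sqrt(sum((heel[ff$frame[i] + 1, 1:2] - c(ff$x[i], ff$y[i]))^2)),
              1e-3)
  }
})

test_that("a negative lateral offset gives a crossover (negative nominal stride width)", {
  tr <- generate_trial(quick_scenario(90, step_width_offset = -0.07))
  expect_lt(tr$truth$nominal$stride_width, 0)
})

test_that("scenarios whose turn arc is shorter than two steps are rejected", {
  sc <- quick_scenario(90, turn_radius = 0.5, step_length = 0.6)
  expect_error(generate_trial(sc), "shorter than 2 steps")
  expect_error(gait_scenario(stance_fraction = 0.9), "stance_fraction")
  expect_error(gait_scenario(step_interval = -1))
})

test_that("trial generation is deterministic, including measurement noise", {
  sc <- quick_scenario(90, noise_sd = 0.002, seed = 11L)
  a <- generate_trial(sc)
  b <- generate_trial(sc)
  expect_identical(a$recording$markers, b$recording$markers)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("cohorts are reproducible and collapse when random effects vanish", {
  des <- cohort_design(n_subjects = 3, n_trials = 2,
                       conditions = data.frame(speed = "normal", amplitude = 90),
                       subject_effect_sd = c(cadence = 0, step_length = 0,
                                             stance_fraction = 0,
                                             step_width_offset = 0),
                       trial_effect_sd = c(cadence = 0, step_length = 0,
                                           stance_fraction = 0,
                                           step_width_offset = 0),
                       seed = 5)
  co1 <- generate_cohort(des)
  co2 <- generate_cohort(des)
  noms <- t(vapply(co1$trials, `[[`, numeric(5), "nominal"))
  expect_true(all(apply(noms, 2, function(v) diff(range(v)) == 0)))
  expect_identical(lapply(co1$trials, `[[`, "nominal"),
                   lapply(co2$trials, `[[`, "nominal"))
  s1 <- vapply(co1$trials, function(tr) tr$scenario$seed, integer(1))
  s2 <- vapply(co2$trials, function(tr) tr$scenario$seed, integer(1))
  expect_identical(s1, s2)
})

test_that("cohort cadences recover the normal and slow condition means", {
  cm <- default_condition_means()
  cm <- cm[cm$amplitude == 90, ]
  des <- cohort_design(n_subjects = 8, n_trials = 2,
                       conditions = cm[, c("speed", "amplitude")],
                       condition_means = cm,
                       base_scenario = gait_scenario(approach_length = 3,
                                                     exit_length = 2),
                       seed = 17)
  co <- generate_cohort(des)
  tt <- suppressWarnings(analyze_cohort(co))
  sm <- summarize_cohort(tt)
  for (cond in c("normal", "slow")) {
    target <- cm$cadence[cm$speed == cond]
    vals <- sm$mean[sm$parameter == "cadence" & sm$speed == cond]
    se <- max(sd(vals) / sqrt(length(vals)), 0.5)
    expect_lt(abs(mean(vals) - target), 2 * se + 1)
  }
})
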
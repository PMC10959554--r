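test_that("footfall positions match ground truth and averaging reduces noise", {
  tr <- generate_trial(quick_scenario(90))
  ev <- suppressMessages(gait_events(tr$recording))
  hs <- ev[ev$type == "heel_strike", ]
  ff <- tr$truth$footfalls
  for (i in seq_len(nrow(hs))) {
    pos <- footfall_position(tr$recording, hs[i, ])
    truth <- ff[ff$side == hs$side[i] & abs(ff$time - hs$time[i]) < 0.05, ]
    expect_equal(nrow(truth), 1)
    expect_lt(sqrt(sum((pos - c(truth$x, truth$y))^2)), 1e-3)
  }
  expect_error(footfall_position(tr$recording,
                                 list(frame = 10 * tr$recording$n_frames,
                                      side = "left")),
               "outside")

  # static foot: the window length does not matter
  rec <- make_standing_recording(duration = 1)
  e <- list(frame = 30L, side = "left")
  expect_identical(footfall_position(rec, e, n_avg = 1L),
                   footfall_position(rec, e, n_avg = 5L))

  # noisy marker: 5-frame averaging beats a single-frame read
  set.seed(1)
  reps <- 300
  single <- replicate(reps, rnorm(1, 0, 0.002))
  averaged <- replicate(reps, mean(rnorm(5, 0, 0.002)))
  expect_lt(var(averaged), var(single))
})

test_that("cadence, duration and step count satisfy their defining identity", {
  for (amp in c(90, 360)) {
    tr <- generate_trial(quick_scenario(amp))
    an <- suppressWarnings(analyze_trial(tr$recording))
    p <- an$parameters
    expect_equal(p[["cadence"]] * p[["turn_duration"]] / 60 + 1, p[["n_steps"]],
                 tolerance = 1e-12)
    expect_lt(abs(p[["cadence"]] - tr$truth$nominal$cadence), 1)
    expect_lt(abs(p[["speed"]] - tr$truth$nominal$speed), 0.02)
  }
})

test_that("uniform gait over a straight window recovers the configured geometry", {
  sc <- quick_scenario(0, step_length = 0.62, step_width_offset = 0.11,
                       approach_length = 6, exit_length = 2)
  tr <- generate_trial(sc)
  ev <- suppressMessages(gait_events(tr$recording))
  seg <- fake_segment(2.0, 4.5)
  legs <- suppressWarnings(per_leg_parameters(tr$recording, ev, seg))
  for (leg in c("internal", "external")) {
    df <- legs[[leg]]
    expect_gt(nrow(df), 0)
    expect_equal(mean(df$stride_length), 2 * 0.62, tolerance = 1e-6)
    expect_equal(mean(df$step_length), 0.62, tolerance = 1e-3)
    expect_equal(mean(df$stride_width), 0.11, tolerance = 1e-3)
    expect_equal(mean(df$cycle), 2 * sc$step_interval, tolerance = 0.01)
  }
})

test_that("stance timing recovers the configured stance fraction", {
  sc <- quick_scenario(90, step_interval = 0.52, stance_fraction = 0.6031)
  tr <- generate_trial(sc)
  an <- suppressWarnings(analyze_trial(tr$recording))
  expect_equal(an$parameters[["stance_internal"]], 0.6031 * 1.04,
               tolerance = 0.02)
  expect_equal(an$parameters[["stance_ratio_internal"]], 60.31,
               tolerance = 0.017)
  expect_lt(an$parameters[["double_support_internal"]],
            an$parameters[["stance_internal"]])
})

test_that("a crossover gait yields a negative external stride width and a wide gait a positive one", {
  cross <- suppressWarnings(analyze_trial(generate_trial(
    gait_scenario(90, turn_radius = 1.8, step_width_offset = -0.20))$recording))
  wide <- suppressWarnings(analyze_trial(generate_trial(
    gait_scenario(90, turn_radius = 1.8, step_width_offset = 0.12))$recording))
  expect_lt(cross$parameters[["stride_width_external"]], 0)
  expect_gt(wide$parameters[["stride_width_external"]], 0)
  expect_gt(wide$parameters[["stride_width_external"]] -
              cross$parameters[["stride_width_external"]], 0.1)
})

test_that("trial aggregation returns the mean and the n-1 within-subject SD", {
  m <- rbind(c(a = 1, b = 5), c(a = 2, b = 5), c(a = 3, b = 5))
  sm <- summarize_trials(m)
  expect_equal(sm$mean[["a"]], 2)
  expect_equal(sm$sd[["a"]], 1)
  expect_equal(sm$sd[["b"]], 0)
  expect_equal(sm$n_trials, 3)

  # within-subject SD of gaussian trial noise has mean c4 * sigma
  set.seed(4)
  sigma <- 0.3
  sds <- replicate(400, sd(rnorm(9, 0, sigma)))
  c4 <- sqrt(2 / 8) * gamma(9 / 2) / gamma(4)
  expect_equal(mean(sds), c4 * sigma, tolerance = 0.02)
})

test_that("bootstrap CIs are sane, deterministic and match the normal theory width", {
  expect_error(bootstrap_ci(1), "at least 2")
  expect_equal(unname(bootstrap_ci(rep(2, 10))), c(2, 2))
  set.seed(2)
  x <- rnorm(100)
  ci1 <- bootstrap_ci(x, n_boot = 4000, seed = 7)
  ci2 <- bootstrap_ci(x, n_boot = 4000, seed = 7)
  expect_identical(ci1, ci2)
  theory <- mean(x) + c(-1, 1) * 1.96 * sd(x) / 10
  expect_lt(max(abs(unname(ci1) - theory)), 0.05)
})

test_that("spatial parameters are invariant to lab-frame rotation and translation", {
  tr <- generate_trial(quick_scenario(90))
  a <- suppressWarnings(analyze_trial(tr$recording))
  b <- suppressWarnings(analyze_trial(
    transform_recording(tr$recording, angle_deg = 63, offset = c(-4, 2, 0))))
  expect_equal(a$parameters, b$parameters, tolerance = 1e-9)
})
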
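# Shared fixtures, all built in code.

# Compact walk-turn-walk scenario (short approach/exit keeps tests fast).
quick_scenario <- function(amplitude = 90, ...) {
  args <- list(...)
  defaults <- list(turn_amplitude = amplitude, approach_length = 3,
                   exit_length = 2)
  do.call(gait_scenario, utils::modifyList(defaults, args))
}

# A standing (or uniformly yawing) subject: pelvis rectangle + feet flat
# on the ground, optionally rotating about the vertical axis.
make_standing_recording <- function(duration = 4, rate = 120,
                                    yaw_fun = function(t) rep(0, length(t))) {
  t <- seq(0, duration, by = 1 / rate)
  psi <- yaw_fun(t) * pi / 180
  u <- cbind(cos(psi), sin(psi))
  nl <- cbind(-sin(psi), cos(psi))
  pel <- function(fw, lat) cbind(fw * u[, 1] + lat * nl[, 1],
                                 fw * u[, 2] + lat * nl[, 2], 1)
  foot <- function(latsign) {
    heel <- cbind(-0.1 * u[, 1] + latsign * 0.1 * nl[, 1],
                  -0.1 * u[, 2] + latsign * 0.1 * nl[, 2], 0)
    toe <- heel + cbind(0.2 * u[, 1], 0.2 * u[, 2], 0)
    list(heel = heel, toe = toe)
  }
  lf <- foot(1); rf <- foot(-1)
  trial_recording(list(L_HEEL = lf$heel, R_HEEL = rf$heel,
                       L_TOE = lf$toe, R_TOE = rf$toe,
                       LASI = pel(0.05, 0.12), RASI = pel(0.05, -0.12),
                       LPSI = pel(-0.05, 0.12), RPSI = pel(-0.05, -0.12)),
                  rate)
}

# Match detected against ground-truth events; returns per-category counts
# and the worst frame error (Inf when counts disagree).
event_match <- function(events, truth) {
  worst <- 0
  count_ok <- TRUE
  for (ty in c("heel_strike", "toe_off")) {
    for (s in c("left", "right")) {
      g <- truth$events[truth$events$type == ty & truth$events$side == s, ]
      d <- events[events$type == ty & events$side == s, ]
      if (nrow(g) != nrow(d)) {
        count_ok <- FALSE
        worst <- Inf
      } else if (nrow(g)) {
        worst <- max(worst, max(abs(g$frame - d$frame)))
      }
    }
  }
  list(count_ok = count_ok, worst = worst)
}

# Brute-force shortest-interval oracle for the HDI.
hdi_bruteforce <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- min(n, max(1L, as.integer(ceiling(mass * n))))
  if (m == n) return(c(x[1], x[n]))
  best <- c(x[1], x[m + 1])
  for (i in seq_len(n - m)) {
    if (x[i + m] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m])
  }
  best
}

# Balanced 2 x 3 repeated-measures response table with a subject random
# intercept; `speed_effect` is added to the slow cells (raw units).
sim_summary_table <- function(seed, n_subjects = 10, speed_effect = 0,
                              subject_sd = 1, resid_sd = 1, mu = 0) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   speed = c("normal", "slow"), amplitude = c(90, 180, 360),
                   stringsAsFactors = FALSE)
  b <- rnorm(n_subjects, 0, subject_sd)
  d$value <- mu + ifelse(d$speed == "slow", speed_effect, 0) +
    b[as.integer(factor(d$subject))] + rnorm(nrow(d), 0, resid_sd)
  d
}

# Model fit with reduced-length-chain warnings and ESS notes silenced
# (tests that exercise the warning mechanism call fit_turn_effects directly).
quiet_fit <- function(...) {
  suppressMessages(suppressWarnings(fit_turn_effects(...)))
}

# Fake turning segment for direct use of the parameter extractors.
fake_segment <- function(window_start, window_end, direction = "left") {
  structure(list(yaw_onset_time = window_start, yaw_offset_time = window_end,
                 window_start_time = window_start, window_end_time = window_end,
                 direction = direction, internal_side = direction,
                 external_side = if (direction == "left") "right" else "left",
                 amplitude_measured = NA_real_, threshold = 30),
            class = "turn_segment")
}
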
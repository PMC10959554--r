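# Scenario and cohort-design descriptions for the synthetic generator.

#' Describe a synthetic walk--turn--walk trial
#'
#' The scenario follows the laboratory protocol geometry: a straight
#' approach, a turn of 90/180/360 degrees (arbitrary angles are allowed)
#' executed around a pivot, and a straight exit. Walking is parameterized
#' by the step interval (time between successive heel strikes of opposite
#' feet), the planar step length, the stance fraction of the gait cycle
#' and a signed lateral foot-placement offset whose negative values
#' produce a crossover pattern (the foot lands across the contralateral
#' progression line, giving a negative stride width).
#'
#' @param turn_amplitude total heading change in degrees (>= 0; 0 is a
#'   straight walk). The study conditions use 90, 180 and 360.
#' @param turn_direction `"left"` (counterclockwise) or `"right"`.
#' @param step_interval time between successive heel strikes of opposite
#'   feet, seconds; cadence is `60 / step_interval` steps/min.
#' @param stance_fraction stance duration / gait-cycle duration, in
#'   (0.5, 0.8): both feet must overlap on the ground, as in walking.
#' @param step_length progression distance per step, m. Consecutive
#'   same-leg contacts are exactly `2 * step_length` apart in the plane.
#' @param step_width_offset signed lateral foot placement offset, m: the
#'   nominal stride width. Negative values give a crossover pattern.
#' @param turn_radius radius of the pelvis path arc during the turn, m.
#' @param approach_length straight approach before the turn, m (the
#'   protocol uses a 5 m approach).
#' @param exit_length straight exit after the turn, m (>= 3 m in the
#'   protocol).
#' @param sampling_rate marker sampling rate, Hz (protocol: 120).
#' @param noise_sd additive i.i.d. Gaussian measurement noise per marker
#'   coordinate per frame, m.
#' @param seed integer seed for the measurement noise.
#' @return an object of class `gait_scenario`.
#' @examples
#' sc <- gait_scenario(turn_amplitude = 90, step_interval = 60 / 113)
#' trial <- generate_trial(sc)
#' @export
gait_scenario <- function(turn_amplitude = 90,
                          turn_direction = c("left", "right"),
                          step_interval = 0.531,
                          stance_fraction = 0.603,
                          step_length = 0.60,
                          step_width_offset = 0.10,
                          turn_radius = 1.0,
                          approach_length = 5,
                          exit_length = 3,
                          sampling_rate = 120,
                          noise_sd = 0,
                          seed = 1L) {
  turn_direction <- match.arg(turn_direction)
  stopifnot(is.numeric(turn_amplitude), length(turn_amplitude) == 1L,
            turn_amplitude >= 0,
            is.numeric(step_interval), step_interval > 0,
            is.numeric(step_length), step_length > 0,
            is.numeric(turn_radius), turn_radius > 0,
            is.numeric(approach_length), approach_length > 0,
            is.numeric(exit_length), exit_length > 0,
            is.numeric(sampling_rate), sampling_rate > 0,
            is.numeric(noise_sd), noise_sd >= 0)
  if (!is.numeric(stance_fraction) || stance_fraction <= 0.5 || stance_fraction >= 0.8)
    stop("`stance_fraction` must lie in (0.5, 0.8): walking requires double support")
  structure(list(turn_amplitude = turn_amplitude,
                 turn_direction = turn_direction,
                 step_interval = step_interval,
                 stance_fraction = stance_fraction,
                 step_length = step_length,
                 step_width_offset = step_width_offset,
                 turn_radius = turn_radius,
                 approach_length = approach_length,
                 exit_length = exit_length,
                 sampling_rate = sampling_rate,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gait_scenario")
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf(
    "<gait_scenario> %g deg %s turn, cadence %.1f steps/min, step %.3f m, stance %.1f%%\n",
    x$turn_amplitude, x$turn_direction, 60 / x$step_interval,
    x$step_length, 100 * x$stance_fraction))
  cat(sprintf("  radius %.2f m, approach %g m, exit %g m, %g Hz, noise sd %g m, seed %d\n",
              x$turn_radius, x$approach_length, x$exit_length,
              x$sampling_rate, x$noise_sd, x$seed))
  invisible(x)
}

#' Default per-condition generator means
#'
#' One row per speed x amplitude condition with the generator parameters
#' that realize the study's observed operating points: cadence and step
#' length chosen so that `speed = step_length * cadence / 60` matches the
#' condition means, stance fraction matching the internal-leg
#' stance/cycle ratio, and a negative lateral offset (crossover) as seen
#' in the external-leg stride width.
#'
#' @return data.frame with columns `speed`, `amplitude`, `cadence`,
#'   `step_length`, `stance_fraction`, `step_width_offset`.
#' @export
default_condition_means <- function() {
  data.frame(
    speed = rep(c("normal", "slow"), each = 3L),
    amplitude = rep(c(90, 180, 360), 2L),
    cadence = c(113, 111, 112, 93, 92, 94),
    step_length = c(0.600, 0.535, 0.471, 0.568, 0.509, 0.460),
    stance_fraction = c(0.6031, 0.6179, 0.6248, 0.6247, 0.6391, 0.6439),
    step_width_offset = c(-0.072, -0.136, -0.159, -0.091, -0.116, -0.126),
    stringsAsFactors = FALSE)
}

#' Describe a synthetic cohort
#'
#' A cohort of `n_subjects` subjects, each recorded for `n_trials` trials
#' in every speed x amplitude condition. Per-trial generator parameters
#' are condition mean + a subject random effect (drawn once per subject)
#' + i.i.d. trial noise, mirroring a repeated-measures design with a
#' subject random intercept. Each subject keeps a fixed randomized turn
#' direction across all of their trials, as in the protocol.
#'
#' @param n_subjects number of subjects (>= 2; study: 10).
#' @param n_trials trials per subject and condition (>= 1; study: 9).
#' @param conditions data.frame with columns `speed` and `amplitude`;
#'   defaults to the full 2 x 3 grid.
#' @param condition_means data.frame as [default_condition_means()].
#' @param subject_effect_sd,trial_effect_sd named numeric vectors of
#'   between-subject and within-subject standard deviations for
#'   `cadence` (steps/min), `step_length` (m), `stance_fraction` and
#'   `step_width_offset` (m).
#' @param base_scenario template [gait_scenario()] supplying geometry
#'   (radius, approach/exit, sampling rate, noise).
#' @param seed integer master seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 10L,
                          n_trials = 9L,
                          conditions = NULL,
                          condition_means = default_condition_means(),
                          subject_effect_sd = c(cadence = 2.0, step_length = 0.020,
                                                stance_fraction = 0.005,
                                                step_width_offset = 0.015),
                          trial_effect_sd = c(cadence = 2.9, step_length = 0.030,
                                              stance_fraction = 0.011,
                                              step_width_offset = 0.030),
                          base_scenario = gait_scenario(),
                          seed = 1L) {
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2")
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  if (is.null(conditions))
    conditions <- condition_means[, c("speed", "amplitude")]
  pars <- c("cadence", "step_length", "stance_fraction", "step_width_offset")
  for (nm in pars) {
    if (is.na(subject_effect_sd[nm]) || subject_effect_sd[nm] < 0)
      stop(sprintf("subject_effect_sd['%s'] must be a nonnegative number", nm))
    if (is.na(trial_effect_sd[nm]) || trial_effect_sd[nm] < 0)
      stop(sprintf("trial_effect_sd['%s'] must be a nonnegative number", nm))
  }
  missing_cond <- !paste(conditions$speed, conditions$amplitude) %in%
    paste(condition_means$speed, condition_means$amplitude)
  if (any(missing_cond))
    stop("every requested condition needs a row in `condition_means`")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 conditions = conditions,
                 condition_means = condition_means,
                 subject_effect_sd = subject_effect_sd[pars],
                 trial_effect_sd = trial_effect_sd[pars],
                 base_scenario = base_scenario,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d subjects x %d conditions x %d trials (seed %d)\n",
              x$n_subjects, nrow(x$conditions), x$n_trials, x$seed))
  invisible(x)
}
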
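# Whole-turn and per-leg spatiotemporal parameters inside the analysis
# window, plus within-subject aggregation and bootstrap summaries.

#' Planar footfall position of a heel-strike event
#'
#' Horizontal heel-marker position averaged over the five frames
#' following the event; the foot is stationary in stance, so with noisy
#' markers the average has lower variance than a single-frame read.
#'
#' @param recording a [trial_recording()].
#' @param event one-row data.frame (or list) with `frame` and `side`.
#' @param n_avg frames to average (default 5).
#' @return numeric length-2 (x, y) in meters.
#' @export
footfall_position <- function(recording, event, n_avg = 5L) {
  fr <- as.integer(event$frame)
  if (is.na(fr) || fr < 0L || fr > recording$n_frames - 1L)
    stop("event frame lies outside the recording")
  heel <- marker(recording, if (event$side == "left") "L_HEEL" else "R_HEEL")
  rows <- (fr + 1L):min(recording$n_frames, fr + n_avg)
  colMeans(heel[rows, 1:2, drop = FALSE])
}

hs_table <- function(recording, events, side = NULL) {
  ev <- events[events$type == "heel_strike", , drop = FALSE]
  if (!is.null(side)) ev <- ev[ev$side == side, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  if (!nrow(ev)) {
    ev$x <- numeric(0); ev$y <- numeric(0)
    return(ev)
  }
  pos <- t(vapply(seq_len(nrow(ev)),
                  function(i) footfall_position(recording, ev[i, ]),
                  numeric(2)))
  ev$x <- pos[, 1L]; ev$y <- pos[, 2L]
  ev
}

#' Whole-turn parameters
#'
#' Inside the closed analysis window: `duration` is the window length;
#' `n_steps` is the number of step intervals spanning the window,
#' `1 + duration / tau` with `tau` the mean interval between the heel
#' strikes inside the window -- the window opens at a toe-off, so the
#' partial steps in progress at its edges count toward it, and the step
#' count is in general fractional; `cadence` is
#' `60 * (n_steps - 1) / duration` steps/min, so the identity
#' `cadence * duration / 60 + 1 = n_steps` holds exactly by
#' construction; `speed` is the horizontal arc length of the
#' pelvis-centroid path across the window divided by the duration (arc
#' length, not net displacement: a 360-degree turn has near-zero net
#' displacement at a clearly nonzero walking speed).
#'
#' @param recording a [trial_recording()].
#' @param events a `gait_event_series`.
#' @param segment a `turn_segment` from [detect_turn()].
#' @param cutoff low-pass cutoff for the pelvis path, Hz.
#' @return named numeric: `speed` (m/s), `turn_duration` (s),
#'   `n_steps`, `cadence` (steps/min).
#' @export
whole_turn_parameters <- function(recording, events, segment, cutoff = 6) {
  ws <- segment$window_start_time
  we <- segment$window_end_time
  eps <- 1e-9
  hs_t <- events$time[events$type == "heel_strike"]
  hs_in <- sort(hs_t[hs_t >= ws - eps & hs_t <= we + eps])
  if (length(hs_in) < 2L)
    stop("analysis window contains fewer than 2 heel strikes")
  duration <- we - ws
  tau <- (hs_in[length(hs_in)] - hs_in[1L]) / (length(hs_in) - 1L)
  n_steps <- 1 + duration / tau
  cadence <- 60 / tau
  rate <- recording$sampling_rate
  ctr <- (marker(recording, "LASI") + marker(recording, "RASI") +
            marker(recording, "LPSI") + marker(recording, "RPSI")) / 4
  x <- lowpass(ctr[, 1L], rate, cutoff)
  y <- lowpass(ctr[, 2L], rate, cutoff)
  i0 <- as.integer(round(ws * rate)) + 1L
  i1 <- as.integer(round(we * rate)) + 1L
  i0 <- max(1L, i0); i1 <- min(recording$n_frames, i1)
  arclen <- sum(sqrt(diff(x[i0:i1])^2 + diff(y[i0:i1])^2))
  c(speed = arclen / duration, turn_duration = duration,
    n_steps = as.numeric(n_steps), cadence = cadence)
}

# Step length / signed stride width of the step ending at heel strike
# `t0` of side `side`, using the chord between the contralateral
# footfalls bracketing it as the local progression direction. Width is
# positive when the foot lands on its own anatomical side of the
# contralateral progression line, negative for a crossover.
step_geometry <- function(t0, p0, side, contra) {
  prev_i <- which(contra$time < t0 - 1e-9)
  next_i <- which(contra$time > t0 + 1e-9)
  if (!length(prev_i) || !length(next_i))
    return(c(step_length = NA_real_, stride_width = NA_real_))
  a <- unlist(contra[max(prev_i), c("x", "y")])
  b <- unlist(contra[min(next_i), c("x", "y")])
  d <- b - a
  dn <- sqrt(sum(d^2))
  if (dn < 1e-9)
    return(c(step_length = NA_real_, stride_width = NA_real_))
  d <- d / dn
  nleft <- c(-d[2L], d[1L])
  vec <- p0 - a
  w <- sum(vec * nleft)
  c(step_length = sum(vec * d),
    stride_width = if (side == "left") w else -w)
}

#' Per-leg per-cycle spatiotemporal parameters
#'
#' For every gait cycle of each leg beginning at a heel strike inside
#' the analysis window (a short 90-degree window spans only about 3-4
#' steps, so a cycle may complete just beyond the window edge;
#' consecutive heel strikes `HS_i`, `HS_{i+1}` of that leg):
#' cycle duration, stance duration (to the leg's own toe-off), the
#' stance/cycle ratio in percent, initial double-support duration (to
#' the contralateral toe-off), planar stride length between the two
#' footfalls, and the step length / signed stride width of the step
#' ending at `HS_i`, decomposed along the chord between the
#' contralateral footfalls bracketing it.
#'
#' @inheritParams whole_turn_parameters
#' @return list with data.frames `internal` and `external` (one row per
#'   cycle; columns `cycle`, `stance`, `stance_ratio`,
#'   `double_support`, `stride_length`, `step_length`, `stride_width`)
#'   and the window's heel-strike tables.
#' @export
per_leg_parameters <- function(recording, events, segment) {
  ws <- segment$window_start_time
  we <- segment$window_end_time
  eps <- 1e-9
  all_hs <- list(left = hs_table(recording, events, "left"),
                 right = hs_table(recording, events, "right"))
  to_ev <- events[events$type == "toe_off", , drop = FALSE]
  leg_cycles <- function(side) {
    contra_side <- if (side == "left") "right" else "left"
    hs <- all_hs[[side]]
    start_i <- which(hs$time >= ws - eps & hs$time <= we + eps &
                       seq_len(nrow(hs)) < nrow(hs))
    cols <- c("cycle", "stance", "stance_ratio", "double_support",
              "stride_length", "step_length", "stride_width")
    if (!length(start_i)) {
      warning(sprintf("no complete gait cycle for the %s leg inside the analysis window",
                      side))
      return(as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols)))
    }
    out <- vector("list", length(start_i))
    for (ii in seq_along(start_i)) {
      i <- start_i[ii]
      t1 <- hs$time[i]; t2 <- hs$time[i + 1L]
      cyc <- t2 - t1
      own_to <- to_ev$time[to_ev$side == side & to_ev$time > t1 + eps &
                             to_ev$time < t2 - eps]
      stance <- if (length(own_to)) min(own_to) - t1 else NA_real_
      contra_to <- to_ev$time[to_ev$side == contra_side & to_ev$time > t1 + eps &
                                to_ev$time < t2 - eps]
      idb <- if (length(contra_to)) min(contra_to) - t1 else NA_real_
      stride <- sqrt((hs$x[i + 1L] - hs$x[i])^2 +
                       (hs$y[i + 1L] - hs$y[i])^2)
      geom <- step_geometry(t1, c(hs$x[i], hs$y[i]), side,
                            all_hs[[contra_side]])
      out[[ii]] <- data.frame(cycle = cyc, stance = stance,
                             stance_ratio = 100 * stance / cyc,
                             double_support = idb,
                             stride_length = stride,
                             step_length = geom[["step_length"]],
                             stride_width = geom[["stride_width"]])
    }
    do.call(rbind, out)
  }
  list(internal = leg_cycles(segment$internal_side),
       external = leg_cycles(segment$external_side),
       internal_side = segment$internal_side,
       external_side = segment$external_side)
}

#' Analyze one trial end to end
#'
#' Runs event detection, turn segmentation and parameter extraction and
#' returns the per-trial parameter vector together with all
#' intermediate objects.
#'
#' @param recording a [trial_recording()].
#' @param threshold yaw-rate threshold for the turning period, deg/s.
#' @param cutoff low-pass cutoff, Hz.
#' @param prom_frac extremum prominence fraction for event detection.
#' @return object of class `turn_analysis`: list with `events`, `yaw`,
#'   `segment`, `legs` (per-cycle tables) and `parameters`, a named
#'   vector in [PARAMETER_ORDER] (per-cycle values averaged within the
#'   trial).
#' @export
analyze_trial <- function(recording, threshold = 30, cutoff = 6, prom_frac = 0.10) {
  events <- gait_events(recording, cutoff = cutoff, prom_frac = prom_frac)
  yaw <- pelvis_yaw_rate(recording, cutoff = cutoff)
  segment <- detect_turn(yaw, events, threshold = threshold)
  whole <- whole_turn_parameters(recording, events, segment, cutoff = cutoff)
  legs <- per_leg_parameters(recording, events, segment)
  leg_mean <- function(df, col) if (nrow(df)) mean(df[[col]], na.rm = TRUE) else NA_real_
  pars <- c(whole,
            stride_length_internal = leg_mean(legs$internal, "stride_length"),
            stride_length_external = leg_mean(legs$external, "stride_length"),
            step_length_internal = leg_mean(legs$internal, "step_length"),
            step_length_external = leg_mean(legs$external, "step_length"),
            stride_width_internal = leg_mean(legs$internal, "stride_width"),
            stride_width_external = leg_mean(legs$external, "stride_width"),
            cycle_internal = leg_mean(legs$internal, "cycle"),
            cycle_external = leg_mean(legs$external, "cycle"),
            stance_internal = leg_mean(legs$internal, "stance"),
            stance_external = leg_mean(legs$external, "stance"),
            double_support_internal = leg_mean(legs$internal, "double_support"),
            double_support_external = leg_mean(legs$external, "double_support"),
            stance_ratio_internal = leg_mean(legs$internal, "stance_ratio"),
            stance_ratio_external = leg_mean(legs$external, "stance_ratio"))
  structure(list(events = events, yaw = yaw, segment = segment, legs = legs,
                 parameters = pars[PARAMETER_ORDER],
                 metadata = recording$metadata),
            class = "turn_analysis")
}

#' @export
print.turn_analysis <- function(x, ...) {
  cat(sprintf("<turn_analysis> %s turn, %.1f deg; window %.2f s, %g steps\n",
              x$segment$direction, x$segment$amplitude_measured,
              x$parameters[["turn_duration"]], x$parameters[["n_steps"]]))
  cat(sprintf("  speed %.3f m/s, cadence %.1f steps/min\n",
              x$parameters[["speed"]], x$parameters[["cadence"]]))
  invisible(x)
}

#' Aggregate the trials of one subject and condition
#'
#' Per-cycle series are averaged within each trial by
#' [analyze_trial()]; this function then takes, per parameter, the mean
#' and the within-subject standard deviation (sample SD, n - 1
#' denominator) across trials -- the variability estimate used for the
#' SD outcome family.
#'
#' @param trial_parameters matrix or data.frame, one row per trial,
#'   named parameter columns.
#' @return list with named vectors `mean` and `sd`, and `n_trials`.
#' @export
summarize_trials <- function(trial_parameters) {
  m <- as.matrix(trial_parameters)
  if (nrow(m) < 1L) stop("at least one trial is required")
  list(mean = colMeans(m, na.rm = TRUE),
       sd = apply(m, 2L, sd, na.rm = TRUE),
       n_trials = nrow(m))
}

#' Analyze every trial of a cohort
#'
#' @param cohort a `gait_cohort` from [generate_cohort()]; trials
#'   without stored trajectories are synthesized on the fly from their
#'   scenarios.
#' @param ... passed to [analyze_trial()].
#' @return data.frame, one row per trial: `subject`, `speed_condition`,
#'   `amplitude`, `trial`, then the parameter columns (the condition
#'   label avoids the name of the walking-speed parameter).
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gait_cohort"))
  rows <- lapply(cohort$trials, function(tr) {
    rec <- tr$recording
    if (is.null(rec)) rec <- generate_trial(tr$scenario)$recording
    an <- analyze_trial(rec, ...)
    cbind(data.frame(subject = tr$subject, speed_condition = tr$speed,
                     amplitude = tr$amplitude, trial = tr$trial,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(an$parameters)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subject, per-condition summary table
#'
#' @param trial_table data.frame from [analyze_cohort()].
#' @return long data.frame: `subject`, `speed`, `amplitude`,
#'   `parameter`, `mean`, `sd`, `n_trials`.
#' @export
summarize_cohort <- function(trial_table) {
  pars <- intersect(PARAMETER_ORDER, colnames(trial_table))
  keys <- unique(trial_table[, c("subject", "speed_condition", "amplitude")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- trial_table$subject == keys$subject[i] &
      trial_table$speed_condition == keys$speed_condition[i] &
      trial_table$amplitude == keys$amplitude[i]
    sm <- summarize_trials(trial_table[sel, pars, drop = FALSE])
    data.frame(subject = keys$subject[i], speed = keys$speed_condition[i],
               amplitude = keys$amplitude[i], parameter = pars,
               mean = unname(sm$mean[pars]), sd = unname(sm$sd[pars]),
               n_trials = sm$n_trials, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile bootstrap CI of a mean
#'
#' @param values numeric vector (n >= 2).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed; the interval is deterministic given it.
#' @return named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 2000L, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("bootstrap_ci needs at least 2 values")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  means <- rowMeans(matrix(values[idx], nrow = n_boot))
  qs <- quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  c(low = qs[1L], high = qs[2L])
}

#' Across-subject condition table with bootstrap CIs
#'
#' Collapses a per-subject summary to the across-subject mean with a
#' percentile-bootstrap CI per parameter and condition, for the mean or
#' the within-subject-SD outcome family.
#'
#' @param subject_summary data.frame from [summarize_cohort()].
#' @param value `"mean"` or `"sd"`: which per-subject quantity to
#'   aggregate.
#' @param level CI level.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return long data.frame: `parameter`, `speed`, `amplitude`, `mean`,
#'   `ci_low`, `ci_high` (ready for [write_results_table()]).
#' @export
condition_table <- function(subject_summary, value = c("mean", "sd"),
                            level = 0.95, n_boot = 2000L, seed = 1L) {
  value <- match.arg(value)
  keys <- unique(subject_summary[, c("parameter", "speed", "amplitude")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- subject_summary$parameter == keys$parameter[i] &
      subject_summary$speed == keys$speed[i] &
      subject_summary$amplitude == keys$amplitude[i]
    v <- subject_summary[[value]][sel]
    ci <- if (sum(!is.na(v)) >= 2L)
      bootstrap_ci(v, level = level, n_boot = n_boot, seed = seed + i)
    else c(low = NA_real_, high = NA_real_)
    data.frame(parameter = keys$parameter[i], speed = keys$speed[i],
               amplitude = keys$amplitude[i], mean = mean(v, na.rm = TRUE),
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
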
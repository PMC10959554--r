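# Synthetic walk--turn--walk marker trajectories with exact ground truth.
#
# Construction, in order:
#   1. A midline path: straight approach, circular arc of the requested
#      radius subtending the turn amplitude, straight exit. The pelvis
#      centroid traverses it at the constant speed step_length /
#      step_interval, yaw-aligned with the path tangent.
#   2. Footfalls: one per step interval, snapped to the frame grid,
#      alternating sides. Positions are chained so that consecutive
#      same-leg contacts are EXACTLY 2 * step_length apart in the plane
#      (equal chord): q[k] = q[k-2] + 2L * u(mean heading of steps k-1, k),
#      with the two chains seeded step_width_offset apart laterally.
#      Planar (Euclidean) stride length is therefore the configured value
#      even through the turn, which is what footfall-based gait analysis
#      measures; equal ARC placement would make measured strides shorter
#      than configured on any arc tight enough to trip the 30 deg/s rule.
#   3. Foot marker series: heel and toe ride a rigid 0.20 m foot axis,
#      exactly stationary and flat on the ground during stance. Swing
#      translates the foot to its next pose with a fast-start sine
#      profile (the foot immediately outruns the pelvis, so the toe's
#      forward coordinate in the pelvis frame is minimal exactly at
#      toe-off) and lifts it by a half-sine of peak 0.05 m (descent rate
#      is maximal exactly at contact, so the foot-center vertical
#      velocity minimum falls on the contact frame).

path_funs <- function(scenario) {
  R <- scenario$turn_radius
  alpha <- scenario$turn_amplitude * pi / 180
  sgn <- if (scenario$turn_direction == "left") 1 else -1
  s0 <- scenario$approach_length
  s1 <- s0 + R * alpha
  heading <- function(s) {
    h <- numeric(length(s))
    inarc <- s > s0 & s <= s1
    h[inarc] <- sgn * (s[inarc] - s0) / R
    h[s > s1] <- sgn * alpha
    h
  }
  pos <- function(s) {
    x <- s
    y <- numeric(length(s))
    inarc <- s > s0 & s <= s1
    post <- s > s1
    if (any(inarc)) {
      phi <- (s[inarc] - s0) / R
      x[inarc] <- s0 + R * sin(phi)
      y[inarc] <- sgn * R * (1 - cos(phi))
    }
    if (any(post)) {
      xe <- s0 + R * sin(alpha)
      ye <- sgn * R * (1 - cos(alpha))
      x[post] <- xe + (s[post] - s1) * cos(sgn * alpha)
      y[post] <- ye + (s[post] - s1) * sin(sgn * alpha)
    }
    cbind(x, y)
  }
  list(pos = pos, heading = heading, total = s1 + scenario$exit_length)
}

#' Generate one synthetic trial with ground truth
#'
#' Synthesizes the eight-marker trajectory of a walk--turn--walk trial
#' (see [gait_scenario()]) together with the exact event times, footfall
#' positions and nominal parameter values the construction implies.
#'
#' The feet are exactly stationary during stance; the pelvis centroid
#' moves at constant path speed `step_length / step_interval` with its
#' yaw following the path tangent, so the total yaw change equals the
#' turn amplitude. Heel-strike and toe-off times are placed on the frame
#' grid (cumulative times rounded to the nearest frame, so intervals
#' alternate around the configured step interval without drift).
#'
#' @param scenario a [gait_scenario()].
#' @return list with elements `recording` (a [trial_recording()]) and
#'   `truth` (class `gait_ground_truth`: `$events` data.frame with
#'   time/frame/side/type, `$footfalls` data.frame, `$nominal` list of
#'   configured parameter values, `$scenario`).
#' @export
generate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  sc <- scenario
  L <- sc$step_length; tau <- sc$step_interval; sf <- sc$stance_fraction
  rate <- sc$sampling_rate; rad <- sc$turn_radius
  alpha <- sc$turn_amplitude * pi / 180
  arc_len <- rad * alpha
  if (sc$turn_amplitude > 0 && arc_len < 2 * L)
    stop(sprintf(
      "turn arc (%.2f m) is shorter than 2 steps (%.2f m): increase turn_radius or amplitude",
      arc_len, 2 * L))
  pf <- path_funs(sc)
  S <- pf$total
  v <- L / tau
  # the pelvis starts 2L behind the path origin (straight extension), so
  # both feet hold a full stance before their first toe-off
  lead <- 2L
  n <- as.integer(floor(((S + lead * L) / v) * rate)) + 1L
  tvec <- (seq_len(n) - 1L) / rate

  ## ---- footfall schedule -------------------------------------------------
  K <- as.integer(floor(S / L))
  f_of <- function(k) as.integer(round((k + lead) * tau * rate))            # HS
  g_of <- function(k) as.integer(round((k + lead + 2 * sf) * tau * rate))   # TO
  while (K >= 1L && f_of(K) > n - 6L) K <- K - 1L  # keep a short stance tail
  if (K < 4L) stop("trial too short: fewer than 4 steps fit on the path")
  kk <- -1L:K
  sidesign <- ifelse(kk %% 2L == 0L, 1L, -1L)      # even steps: left foot
  side_k <- ifelse(sidesign > 0L, "left", "right")
  SW <- sc$step_width_offset

  nvec <- function(psi) cbind(-sin(psi), cos(psi)) # left normal
  uvec <- function(psi) cbind(cos(psi), sin(psi))
  # Footfalls are lateral offsets from a midline chain; each midline
  # advance d is the positive root of a quadratic chosen so that the
  # planar distance between consecutive same-leg contacts is exactly
  # 2L, also through the turn (|m_{k-1} + d u + off_k - q_{k-2}| = 2L).
  # Headings follow a step-indexed schedule: the turn is executed over
  # n_t = round(arc / L) steps, each rotating the heading by
  # amplitude / n_t, between the approach and exit steps (a monotone
  # schedule; indexing by chain length would feed the solved step
  # lengths back into the headings and can oscillate on tight turns).
  sgn <- if (sc$turn_direction == "left") 1 else -1
  k_turn0 <- max(1L, as.integer(floor(sc$approach_length / L)))
  n_t <- if (sc$turn_amplitude > 0) max(2L, as.integer(round(arc_len / L))) else 0L
  step_heading <- function(k) {
    if (n_t == 0L) return(0)
    sgn * alpha * min(max(k - k_turn0, 0L), n_t) / n_t
  }
  psi_k <- vapply(kk, step_heading, numeric(1))
  q <- matrix(NA_real_, length(kk), 2L)
  rownames(q) <- as.character(kk)
  q[1L, ] <- pf$pos(-L) + sidesign[1L] * (SW / 2) * as.numeric(nvec(psi_k[1L]))
  q[2L, ] <- pf$pos(0) + sidesign[2L] * (SW / 2) * as.numeric(nvec(psi_k[2L]))
  for (i in 3L:length(kk)) {
    theta <- (psi_k[i - 1L] + psi_k[i]) / 2
    q[i, ] <- q[i - 2L, ] + 2 * L * c(cos(theta), sin(theta))
  }

  ## ---- foot marker series ------------------------------------------------
  foot_len <- 0.20
  lift <- 0.05
  make_foot <- function(first_k) {
    ks <- seq(first_k, K, by = 2L)
    heel <- matrix(NA_real_, n, 3L)
    toe <- matrix(NA_real_, n, 3L)
    for (j in seq_along(ks)) {
      k <- ks[j]
      i <- k + 2L  # row in q / psi_k
      hs_f <- if (j == 1L) 0L else max(f_of(k), 0L)
      to_f <- if (j < length(ks)) g_of(k) else n - 1L
      to_f <- min(to_f, n - 1L)
      rows <- (hs_f:to_f) + 1L
      heel[rows, 1L] <- q[i, 1L]; heel[rows, 2L] <- q[i, 2L]; heel[rows, 3L] <- 0
      tx <- q[i, ] + foot_len * c(cos(psi_k[i]), sin(psi_k[i]))
      toe[rows, 1L] <- tx[1L]; toe[rows, 2L] <- tx[2L]; toe[rows, 3L] <- 0
      if (j < length(ks)) {
        nxt_f <- f_of(k + 2L)
        if (nxt_f > to_f + 1L) {
          fr <- (to_f + 1L):(nxt_f - 1L)
          phi <- (fr - to_f) / (nxt_f - to_f)
          prog <- sin(pi * phi / 2)          # fast start, soft landing
          hx <- q[i, 1L] + (q[i + 2L, 1L] - q[i, 1L]) * prog
          hy <- q[i, 2L] + (q[i + 2L, 2L] - q[i, 2L]) * prog
          hz <- lift * sin(pi * phi)         # max descent rate at contact
          psis <- psi_k[i] + (psi_k[i + 2L] - psi_k[i]) * prog
          heel[fr + 1L, ] <- cbind(hx, hy, hz)
          toe[fr + 1L, ] <- cbind(hx + foot_len * cos(psis),
                                  hy + foot_len * sin(psis), hz)
        }
      }
    }
    list(heel = heel, toe = toe)
  }
  left <- make_foot(0L)
  right <- make_foot(-1L)

  ## ---- pelvis marker series ----------------------------------------------
  sp <- v * tvec - lead * L
  P <- pf$pos(sp)
  psi_p <- pf$heading(sp)
  up <- uvec(psi_p); np <- nvec(psi_p)
  zp <- rep(1.0, n)
  pelvis <- function(fw, lat) cbind(P[, 1L] + fw * up[, 1L] + lat * np[, 1L],
                                    P[, 2L] + fw * up[, 2L] + lat * np[, 2L], zp)
  markers <- list(
    L_HEEL = left$heel, R_HEEL = right$heel,
    L_TOE = left$toe, R_TOE = right$toe,
    LASI = pelvis(0.05, 0.12), RASI = pelvis(0.05, -0.12),
    LPSI = pelvis(-0.05, 0.12), RPSI = pelvis(-0.05, -0.12))

  if (sc$noise_sd > 0) {
    set.seed(sc$seed)
    markers <- lapply(markers, function(m) m + rnorm(length(m), 0, sc$noise_sd))
  }

  ## ---- ground truth ------------------------------------------------------
  hs_k <- kk[kk >= 1L]
  to_k <- kk[kk + 2L <= K]
  ev <- rbind(
    data.frame(time = f_of(hs_k) / rate, frame = f_of(hs_k),
               side = side_k[match(hs_k, kk)], type = "heel_strike",
               stringsAsFactors = FALSE),
    data.frame(time = pmax(g_of(to_k), 1L) / rate, frame = pmax(g_of(to_k), 1L),
               side = side_k[match(to_k, kk)], type = "toe_off",
               stringsAsFactors = FALSE))
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]
  rownames(ev) <- NULL
  footfalls <- data.frame(step = kk, side = side_k,
                          time = f_of(kk) / rate, frame = f_of(kk),
                          x = q[, 1L], y = q[, 2L], heading = psi_k,
                          stringsAsFactors = FALSE)
  nominal <- list(step_length = L, stride_length = 2 * L,
                  step_interval = tau, cadence = 60 / tau, speed = v,
                  cycle_duration = 2 * tau, stance_duration = 2 * tau * sf,
                  stance_ratio = 100 * sf,
                  double_support = (2 * sf - 1) * tau,
                  stride_width = SW,
                  turn_amplitude = sc$turn_amplitude,
                  turn_direction = sc$turn_direction)
  truth <- structure(list(events = ev, footfalls = footfalls,
                          nominal = nominal, scenario = sc),
                     class = "gait_ground_truth")
  recording <- trial_recording(
    markers, rate,
    metadata = list(amplitude = sc$turn_amplitude,
                    direction = sc$turn_direction,
                    synthetic = TRUE))
  list(recording = recording, truth = truth)
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> %d events, %d footfalls, %g deg %s turn\n",
              nrow(x$events), nrow(x$footfalls),
              x$nominal$turn_amplitude, x$nominal$turn_direction))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject random effects and per-trial noise around the
#' per-condition generator means of the design, builds one scenario per
#' trial, and (optionally) synthesizes the marker trajectories. The
#' whole cohort is reproducible from the design seed.
#'
#' @param design a [cohort_design()].
#' @param trajectories if `TRUE`, marker data are generated eagerly for
#'   every trial (memory heavy for full cohorts); if `FALSE` only the
#'   scenarios and their nominal parameter values are returned, and
#'   trials can be synthesized later with [generate_trial()].
#' @return object of class `gait_cohort`: `$trials` is a list with one
#'   element per trial (`subject`, `speed`, `amplitude`, `trial`,
#'   `scenario`, `nominal`, and -- when requested -- `recording`,
#'   `truth`); `$design` echoes the design.
#' @export
generate_cohort <- function(design, trajectories = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  ns <- design$n_subjects
  pars <- names(design$subject_effect_sd)
  subj_eff <- sapply(pars, function(p) rnorm(ns, 0, design$subject_effect_sd[[p]]))
  directions <- sample(c("left", "right"), ns, replace = TRUE)
  base <- design$base_scenario
  cm <- design$condition_means
  trials <- list()
  idx <- 0L
  for (s in seq_len(ns)) {
    for (ci in seq_len(nrow(design$conditions))) {
      cond <- design$conditions[ci, ]
      row <- cm[cm$speed == cond$speed & cm$amplitude == cond$amplitude, ][1L, ]
      for (tr in seq_len(design$n_trials)) {
        val <- vapply(pars, function(p)
          unname(row[[p]] + subj_eff[s, p] +
                   rnorm(1, 0, design$trial_effect_sd[[p]])), numeric(1))
        cadence <- min(max(val[["cadence"]], 40), 200)
        stepl <- min(max(val[["step_length"]], 0.2), 1.2)
        sfrac <- min(max(val[["stance_fraction"]], 0.52), 0.78)
        sw <- min(max(val[["step_width_offset"]], -0.4), 0.4)
        sc <- gait_scenario(
          turn_amplitude = cond$amplitude,
          turn_direction = directions[s],
          step_interval = 60 / cadence,
          stance_fraction = sfrac,
          step_length = stepl,
          step_width_offset = sw,
          turn_radius = base$turn_radius,
          approach_length = base$approach_length,
          exit_length = base$exit_length,
          sampling_rate = base$sampling_rate,
          noise_sd = base$noise_sd,
          seed = sample.int(.Machine$integer.max - 1L, 1L))
        idx <- idx + 1L
        rec <- NULL; truth <- NULL
        if (trajectories) {
          gen <- generate_trial(sc)
          rec <- gen$recording; truth <- gen$truth
          rec$metadata$subject <- sprintf("S%02d", s)
          rec$metadata$speed <- cond$speed
          rec$metadata$trial <- tr
        }
        trials[[idx]] <- list(
          subject = sprintf("S%02d", s),
          speed = cond$speed, amplitude = cond$amplitude, trial = tr,
          scenario = sc,
          nominal = c(cadence = cadence, step_length = stepl,
                      stance_fraction = sfrac, step_width_offset = sw,
                      speed = stepl * cadence / 60),
          recording = rec, truth = truth)
      }
    }
  }
  structure(list(trials = trials, design = design), class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials (%d subjects, %d conditions, %d trials each)\n",
              length(x$trials), x$design$n_subjects,
              nrow(x$design$conditions), x$design$n_trials))
  invisible(x)
}
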
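# Gait-event detection from marker kinematics.
#
# Heel strikes follow the foot-velocity principle (minima of the
# foot-center vertical velocity, gated to frames where the foot's
# forward velocity in the pelvis frame is low), toe-offs the
# coordinate principle (minima of the toe's forward coordinate in the
# pelvis frame). Both are expressed in a pelvis-local progression frame
# so the detectors stay valid through 90/180/360-degree turns, where a
# fixed lab axis has no meaning. Signals are low-pass filtered
# (zero-phase Butterworth, 6 Hz) before differentiation; each filtered
# candidate is refined to the raw-signal extremum, and heel strikes are
# additionally snapped to the first frame at which the heel settles
# onto its stance level, which restores frame-exact timing around the
# smoothed velocity kink at contact.

#' Per-frame pelvis reference frame
#'
#' Origin is the centroid of the four pelvis markers. The lateral axis
#' points from the right to the left anterior iliac-spine marker,
#' projected to the ground plane and normalized; the forward axis is the
#' horizontal direction the pelvis faces (lateral x vertical); both are
#' unit length and orthogonal.
#'
#' @param recording a [trial_recording()] with the pelvis markers.
#' @return list of n x 3 matrices `origin`, `forward`, `lateral`.
#' @export
pelvis_frame <- function(recording) {
  for (m in c("LASI", "RASI", "LPSI", "RPSI")) marker(recording, m)
  origin <- (marker(recording, "LASI") + marker(recording, "RASI") +
               marker(recording, "LPSI") + marker(recording, "RPSI")) / 4
  lat <- marker(recording, "LASI") - marker(recording, "RASI")
  lat[, 3L] <- 0
  len <- sqrt(rowSums(lat^2))
  if (any(len < 1e-6))
    stop("degenerate pelvis geometry: LASI and RASI coincide in the ground plane")
  lat <- lat / len
  fwd <- cbind(lat[, 2L], -lat[, 1L], 0)  # lateral x vertical(z)
  list(origin = origin, forward = fwd, lateral = lat)
}

# Forward coordinate of a point series relative to the pelvis, per frame.
pelvis_forward_coord <- function(xy, frame) {
  rel <- xy - frame$origin[, 1:2, drop = FALSE]
  rowSums(rel * frame$forward[, 1:2, drop = FALSE])
}

event_df <- function(frames, rate, side, type) {
  data.frame(time = frames / rate, frame = as.integer(frames),
             side = rep_len(side, length(frames)),
             type = rep_len(type, length(frames)),
             stringsAsFactors = FALSE)
}

# Shared candidate logic: minima of `sig_f` (filtered) with prominence
# above prom_frac of the signal IQR and a refractory of refractory_frac
# of the median candidate spacing (earlier frame kept).
extremum_candidates <- function(sig_f, prom_frac = 0.10, refractory_frac = 0.4) {
  iqr <- diff(quantile(sig_f, c(0.25, 0.75), names = FALSE))
  prom <- max(prom_frac * iqr, 1e-6)  # floor kills numerical ripple on flat signals
  cand <- local_minima(sig_f, min_prominence = prom)
  if (length(cand) > 2L) {
    refr <- as.integer(floor(refractory_frac * median(diff(cand))))
    cand <- local_minima(sig_f, min_prominence = prom, refractory = refr)
  }
  cand
}

#' Detect heel strikes of both feet
#'
#' Candidates are minima of the filtered foot-center (midpoint of heel
#' and toe markers) vertical velocity, kept only where the foot's
#' forward velocity in the pelvis frame is below `gate_frac` of its 95th
#' percentile (the foot is about to stop), refined to the raw velocity
#' minimum and snapped to the first frame at which the heel height
#' settles at its stance level.
#'
#' @param recording a [trial_recording()].
#' @param frame pelvis frame from [pelvis_frame()] (computed if omitted).
#' @param cutoff low-pass cutoff, Hz.
#' @param prom_frac minimum peak prominence as a fraction of the
#'   signal's interquartile range.
#' @param gate_frac forward-velocity gate as a fraction of the 95th
#'   percentile of absolute foot forward velocity.
#' @return data.frame with columns `time`, `frame`, `side`, `type`
#'   (`"heel_strike"`); zero rows when nothing is found (e.g. standing).
#' @export
detect_heel_strikes <- function(recording, frame = pelvis_frame(recording),
                                cutoff = 6, prom_frac = 0.05, gate_frac = 0.25) {
  rate <- recording$sampling_rate
  h <- 1 / rate
  out <- list()
  for (side in c("left", "right")) {
    heel <- marker(recording, if (side == "left") "L_HEEL" else "R_HEEL")
    toe <- marker(recording, if (side == "left") "L_TOE" else "R_TOE")
    ctr <- (heel + toe) / 2
    z_f <- lowpass(ctr[, 3L], rate, cutoff)
    vz_f <- central_diff(z_f, h)
    # refinement signal: lightly filtered, so the contact kink stays
    # sharp but measurement noise cannot throw the arg-min
    z_ref <- lowpass(ctr[, 3L], rate, min(15, rate / 3))
    vz_ref <- central_diff(z_ref, h)
    cand <- extremum_candidates(vz_f, prom_frac)
    if (length(cand)) {
      # the landing descent is deep; filter ripple during stance is not
      depth_floor <- 0.3 * quantile(vz_f, 0.01, names = FALSE)
      cand <- cand[vz_f[cand] <= depth_floor]
    }
    if (length(cand)) {
      # foot velocity over ground, projected on the pelvis forward axis:
      # the foot must come (nearly) to a stop shortly after a landing
      # candidate; mid-swing minima keep moving fast
      vx <- central_diff(lowpass(ctr[, 1L], rate, cutoff), h)
      vy <- central_diff(lowpass(ctr[, 2L], rate, cutoff), h)
      vfwd <- abs(vx * frame$forward[, 1L] + vy * frame$forward[, 2L])
      gate <- gate_frac * quantile(vfwd, 0.95, names = FALSE)
      horizon <- as.integer(round(0.15 * rate))
      nfr <- length(vfwd)
      cand <- cand[vapply(cand, function(i)
        min(vfwd[i:min(nfr, i + horizon)]) <= gate, logical(1))]
    }
    if (length(cand)) {
      cand <- refine_to_raw_min(cand, vz_ref, halfwin = 6L)
      cand <- vapply(cand, function(i) snap_to_ground(i, heel[, 3L]), integer(1))
      cand <- sort(unique(cand))
    }
    out[[side]] <- event_df(cand - 1L, rate, side, "heel_strike")
  }
  res <- rbind(out$left, out$right)
  res <- res[order(res$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# From a velocity-minimum candidate (R index), advance to the first
# frame whose heel height is within `tol` of the local stance level
# (median of the following window, which is stance-dominated).
snap_to_ground <- function(i, z, ahead = 12L, tol = NULL) {
  n <- length(z)
  win <- i:min(n, i + 20L)
  floor_z <- median(z[win])
  if (is.null(tol)) {
    sigma <- mad(diff(z)) / sqrt(2)
    tol <- max(0.002, 3 * sigma)
  }
  for (j in i:min(n, i + ahead)) {
    if (z[j] <= floor_z + tol) return(as.integer(j))
  }
  as.integer(i)
}

#' Detect toe-offs of both feet
#'
#' Toe-offs are the minima (most negative excursions) of the toe
#' marker's forward coordinate expressed in the pelvis frame: the foot
#' is maximally behind the pelvis exactly when it leaves the ground.
#' During turning the rotation of the pelvis frame adds a drift
#' (yaw rate times the toe's lateral coordinate) to this signal that
#' can flatten the minimum of the inner foot entirely, so the
#' accumulated rotation contribution is subtracted before the extremum
#' search; in straight walking the correction is identically zero and
#' the detector reduces to the plain coordinate rule.
#'
#' @inheritParams detect_heel_strikes
#' @return data.frame with columns `time`, `frame`, `side`, `type`
#'   (`"toe_off"`); zero rows when nothing is found.
#' @export
detect_toe_offs <- function(recording, frame = pelvis_frame(recording),
                            cutoff = 6, prom_frac = 0.05) {
  rate <- recording$sampling_rate
  h <- 1 / rate
  yaw <- unwrap_rad(atan2(frame$forward[, 2L], frame$forward[, 1L]))
  yaw_rate <- central_diff(lowpass(yaw, rate, cutoff), h)
  out <- list()
  for (side in c("left", "right")) {
    toe <- marker(recording, if (side == "left") "L_TOE" else "R_TOE")
    rel <- toe[, 1:2, drop = FALSE] - frame$origin[, 1:2, drop = FALSE]
    r_fwd <- rowSums(rel * frame$forward[, 1:2, drop = FALSE])
    r_lat <- rowSums(rel * frame$lateral[, 1:2, drop = FALSE])
    r_raw <- r_fwd - cumsum(yaw_rate * r_lat) * h
    r_f <- lowpass(r_raw, rate, cutoff)
    cand <- extremum_candidates(r_f, prom_frac)
    if (length(cand)) {
      cand <- refine_to_raw_min(cand, r_raw, halfwin = 4L)
      cand <- sort(unique(cand))
    }
    out[[side]] <- event_df(cand - 1L, rate, side, "toe_off")
  }
  res <- rbind(out$left, out$right)
  res <- res[order(res$time), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge and validate heel-strike and toe-off events
#'
#' Merges the two event lists, sorts them by time and enforces, per
#' side, the alternation heel-strike / toe-off / heel-strike / ...:
#' when two same-type events of one side follow each other the later
#' one is dropped (and reported via a message and the `"dropped"`
#' attribute).
#'
#' @param hs_events,to_events data.frames from [detect_heel_strikes()]
#'   and [detect_toe_offs()].
#' @return a `gait_event_series` data.frame (`time`, `frame`, `side`,
#'   `type`), with dropped events in `attr(, "dropped")`.
#' @export
merge_and_validate <- function(hs_events, to_events) {
  ev <- rbind(hs_events, to_events)
  if (sum(ev$type == "heel_strike") < 2L)
    stop("insufficient gait: fewer than 2 heel strikes detected")
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  for (side in unique(ev$side)) {
    idx <- which(ev$side == side)
    last_type <- NA_character_
    for (i in idx) {
      if (!is.na(last_type) && ev$type[i] == last_type) {
        keep[i] <- FALSE
      } else {
        last_type <- ev$type[i]
      }
    }
  }
  dropped <- ev[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    message(sprintf("merge_and_validate: dropped %d event(s) violating per-side alternation",
                    nrow(dropped)))
  }
  out <- ev[keep, , drop = FALSE]
  if (sum(out$type == "heel_strike") < 2L)
    stop("insufficient gait: fewer than 2 heel strikes after validation")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("gait_event_series", "data.frame")
  out
}

#' Detect and validate all gait events of a recording
#'
#' Convenience wrapper: pelvis frame, heel strikes, toe-offs,
#' [merge_and_validate()].
#'
#' @inheritParams detect_heel_strikes
#' @return a `gait_event_series` data.frame.
#' @export
gait_events <- function(recording, cutoff = 6, prom_frac = 0.05) {
  frame <- pelvis_frame(recording)
  hs <- detect_heel_strikes(recording, frame, cutoff = cutoff, prom_frac = prom_frac)
  to <- detect_toe_offs(recording, frame, cutoff = cutoff, prom_frac = prom_frac)
  merge_and_validate(hs, to)
}

#' @export
print.gait_event_series <- function(x, ...) {
  cat(sprintf("<gait_event_series> %d events (%d heel strikes, %d toe-offs), %.2f-%.2f s\n",
              nrow(x), sum(x$type == "heel_strike"), sum(x$type == "toe_off"),
              min(x$time), max(x$time)))
  invisible(x)
}
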
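# Turning-period segmentation from pelvis yaw rate.

#' Pelvis yaw angle and yaw rate
#'
#' Yaw is the heading of the pelvis forward axis in the ground plane,
#' unwrapped so a 360-degree turn shows no discontinuity; the rate is
#' the central difference of the filtered yaw.
#'
#' @param recording a [trial_recording()] with pelvis markers.
#' @param cutoff low-pass cutoff for the yaw series, Hz (the same
#'   smoothing convention as the position signals).
#' @return object of class `pelvis_yaw`: data.frame with columns
#'   `time`, `yaw` (deg, filtered, unwrapped) and `rate` (deg/s).
#' @export
pelvis_yaw_rate <- function(recording, cutoff = 6) {
  fr <- pelvis_frame(recording)
  yaw_rad <- unwrap_rad(atan2(fr$forward[, 2L], fr$forward[, 1L]))
  rate_hz <- recording$sampling_rate
  yaw_f <- lowpass(yaw_rad * 180 / pi, rate_hz, cutoff)
  out <- data.frame(time = recording_time(recording),
                    yaw = yaw_f,
                    rate = central_diff(yaw_f, 1 / rate_hz))
  class(out) <- c("pelvis_yaw", "data.frame")
  out
}

#' Detect the turning period and analysis window
#'
#' The turning period is the longest contiguous run of frames whose
#' absolute pelvis yaw rate exceeds `threshold` (30 deg/s by default);
#' runs shorter than `min_duration` are ignored as noise. The analysis
#' window extends the period to the last toe-off before its onset and
#' the first heel strike after its offset. The internal leg is the leg
#' on the side the subject turns toward (left turn = counterclockwise =
#' positive yaw change).
#'
#' @param yaw a `pelvis_yaw` data.frame from [pelvis_yaw_rate()].
#' @param events a `gait_event_series` from [gait_events()].
#' @param threshold yaw-rate threshold, deg/s.
#' @param min_duration minimum supra-threshold run length, s.
#' @return object of class `turn_segment`: list with `yaw_onset_time`,
#'   `yaw_offset_time`, `window_start_time`, `window_end_time`,
#'   `direction`, `internal_side`, `external_side`,
#'   `amplitude_measured` (deg).
#' @export
detect_turn <- function(yaw, events, threshold = 30, min_duration = 0.1) {
  stopifnot(is.data.frame(yaw), all(c("time", "yaw", "rate") %in% names(yaw)))
  supra <- abs(yaw$rate) > threshold
  if (!any(supra)) stop("no turn detected: pelvis yaw rate never exceeds threshold")
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  dt <- median(diff(yaw$time))
  runs <- runs[(runs$end - runs$start + 1L) * dt >= min_duration, , drop = FALSE]
  if (!nrow(runs)) stop("no turn detected: supra-threshold runs all shorter than min_duration")
  best <- runs[which.max(runs$end - runs$start), ]
  onset_t <- yaw$time[best$start]
  offset_t <- yaw$time[best$end]
  dyaw <- yaw$yaw[best$end] - yaw$yaw[best$start]
  direction <- if (dyaw > 0) "left" else "right"
  to_before <- events$time[events$type == "toe_off" & events$time <= onset_t]
  if (!length(to_before))
    stop("missing bounding event: no toe-off before the turn onset")
  hs_after <- events$time[events$type == "heel_strike" & events$time >= offset_t]
  if (!length(hs_after))
    stop("missing bounding event: no heel strike after the turn offset")
  structure(list(yaw_onset_time = onset_t,
                 yaw_offset_time = offset_t,
                 window_start_time = max(to_before),
                 window_end_time = min(hs_after),
                 direction = direction,
                 internal_side = direction,
                 external_side = if (direction == "left") "right" else "left",
                 amplitude_measured = abs(dyaw),
                 threshold = threshold),
            class = "turn_segment")
}

#' @export
print.turn_segment <- function(x, ...) {
  cat(sprintf("<turn_segment> %s turn, %.1f deg measured (|yaw rate| > %g deg/s)\n",
              x$direction, x$amplitude_measured, x$threshold))
  cat(sprintf("  turning period %.3f-%.3f s; analysis window %.3f-%.3f s\n",
              x$yaw_onset_time, x$yaw_offset_time,
              x$window_start_time, x$window_end_time))
  cat(sprintf("  internal leg: %s, external leg: %s\n",
              x$internal_side, x$external_side))
  invisible(x)
}
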
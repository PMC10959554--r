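# TrialRecording container: time-synchronized 3D marker series.

#' Create a trial recording
#'
#' Bundles time-synchronized 3D marker trajectories with their sampling
#' rate. Coordinates are in meters in a right-handed lab frame with the
#' z axis vertical; time runs from frame 0 at `t = frame / rate`.
#'
#' @param markers named list of numeric n x 3 matrices (columns x, y, z),
#'   one per marker; all must have the same number of rows.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param metadata optional named list (subject id, condition, amplitude,
#'   direction, ...) carried along but not interpreted.
#' @return an object of class `trial_recording`.
#' @seealso [read_trc()], [generate_trial()]
#' @export
trial_recording <- function(markers, sampling_rate, metadata = list()) {
  if (!is.list(markers) || is.null(names(markers)) || any(names(markers) == ""))
    stop("`markers` must be a named list of n x 3 matrices")
  if (!length(markers)) stop("recording has no markers")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each marker series must have 3 columns (x, y, z)")
    colnames(m) <- c("x", "y", "z")
    storage.mode(m) <- "double"
    m
  })
  nf <- vapply(markers, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    stop("all marker series must have the same number of frames")
  if (nf[1L] < 1L) stop("recording is empty (zero frames)")
  structure(list(markers = markers,
                 sampling_rate = as.numeric(sampling_rate),
                 n_frames = as.integer(nf[1L]),
                 metadata = metadata),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d markers x %d frames @ %g Hz (%.2f s)\n",
              length(x$markers), x$n_frames, x$sampling_rate,
              (x$n_frames - 1L) / x$sampling_rate))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  if (length(x$metadata)) {
    md <- vapply(x$metadata, function(v) paste(format(v), collapse = ","), character(1))
    cat("  metadata:", paste(names(md), md, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Frame time stamps of a recording
#'
#' @param recording a [trial_recording()].
#' @return numeric vector, `t = (0:(n-1)) / rate` seconds.
#' @export
recording_time <- function(recording) {
  (seq_len(recording$n_frames) - 1L) / recording$sampling_rate
}

#' Extract one marker's trajectory
#'
#' @param recording a [trial_recording()].
#' @param name marker name.
#' @return n x 3 matrix.
#' @export
marker <- function(recording, name) {
  m <- recording$markers[[name]]
  if (is.null(m)) stop(sprintf("missing required marker: %s", name))
  m
}

check_required_markers <- function(recording, required = REQUIRED_MARKERS) {
  missing <- setdiff(required, names(recording$markers))
  if (length(missing))
    stop(sprintf("missing required marker%s: %s",
                 if (length(missing) > 1L) "s" else "",
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Rigidly transform a recording in the horizontal plane
#'
#' Rotates all markers by `angle_deg` about the vertical axis and then
#' translates them; vertical coordinates are unchanged by the rotation.
#' Useful to check that the analysis is invariant to the lab frame.
#'
#' @param recording a [trial_recording()].
#' @param angle_deg rotation about z, degrees counterclockwise.
#' @param offset numeric length-3 translation (m).
#' @return transformed `trial_recording`.
#' @export
transform_recording <- function(recording, angle_deg = 0, offset = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  markers <- lapply(recording$markers, function(m) {
    out <- m %*% t(Rz)
    sweep(out, 2, as.numeric(offset), "+")
  })
  trial_recording(markers, recording$sampling_rate, recording$metadata)
}
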
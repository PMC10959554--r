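# Marker-trajectory file IO: TRC (tab-delimited motion-capture exchange
# format) and a documented CSV layout, plus ground-truth JSON sidecars
# and the results table writer.
#
# Internal canonical units: meters, seconds; frame f (0-based) is at
# t = f / rate. Coordinates are written with 17 significant digits so a
# write/read round trip reproduces the doubles bit-identically.

#' Default marker alias map
#'
#' Maps vendor marker labels to the canonical names in
#' [REQUIRED_MARKERS]. Matching is case-insensitive.
#'
#' @return named list: canonical name -> character vector of aliases.
#' @export
default_marker_aliases <- function() {
  list(
    L_HEEL = c("L_HEEL", "LHEE", "LHEEL", "LCAL", "LEFT_HEEL"),
    R_HEEL = c("R_HEEL", "RHEE", "RHEEL", "RCAL", "RIGHT_HEEL"),
    L_TOE = c("L_TOE", "LTOE", "LMT2", "L_MET2", "LEFT_TOE"),
    R_TOE = c("R_TOE", "RTOE", "RMT2", "R_MET2", "RIGHT_TOE"),
    LASI = c("LASI", "LASIS", "L_ASIS"),
    RASI = c("RASI", "RASIS", "R_ASIS"),
    LPSI = c("LPSI", "LPSIS", "L_PSIS"),
    RPSI = c("RPSI", "RPSIS", "R_PSIS"))
}

normalize_marker_names <- function(names, aliases = default_marker_aliases()) {
  out <- names
  low <- tolower(names)
  for (canon in names(aliases)) {
    hit <- low %in% tolower(aliases[[canon]])
    out[hit] <- canon
  }
  out
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a recording to a TRC file
#'
#' Standard tab-delimited TRC layout: a three-line header
#' (PathFileType; DataRate/CameraRate/NumFrames/NumMarkers/Units/...),
#' two marker-label lines, then one row per frame with 1-based frame
#' number, time, and X/Y/Z triplets per marker. Units are meters.
#'
#' @param recording a [trial_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(recording, path) {
  stopifnot(inherits(recording, "trial_recording"))
  if (!length(recording$markers) || recording$n_frames < 1L)
    stop("cannot write an empty recording")
  nm <- names(recording$markers)
  n <- recording$n_frames
  rate <- recording$sampling_rate
  head1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  head2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                 "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
  head3 <- paste(fmt17(rate), fmt17(rate), n, length(nm), "m",
                 fmt17(rate), 1L, n, sep = "\t")
  lab1 <- paste(c("Frame#", "Time", as.vector(rbind(nm, "", ""))), collapse = "\t")
  lab2 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nm)),
                                 rep(seq_along(nm), each = 3L))), collapse = "\t")
  coords <- do.call(cbind, recording$markers)
  tvec <- recording_time(recording)
  body <- paste(seq_len(n), sprintf("%.6f", tvec),
                apply(coords, 1L, function(r) paste(fmt17(r), collapse = "\t")),
                sep = "\t")
  writeLines(c(head1, head2, head3, lab1, lab2, "", body), con = path)
  invisible(path)
}

#' Read a TRC marker file
#'
#' Parses the standard TRC layout, converts positions to meters
#' (`Units` may be `m` or `mm`), and normalizes marker labels through a
#' configurable alias map.
#'
#' @param path TRC file path.
#' @param aliases alias map as [default_marker_aliases()].
#' @param required if `TRUE` (default) the eight canonical markers must
#'   be present after aliasing; a missing one raises an error naming it.
#' @return a [trial_recording()].
#' @export
read_trc <- function(path, aliases = default_marker_aliases(), required = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L)
    stop(sprintf("not a valid TRC file (only %d lines): %s", length(lines), path))
  hdr_names <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  hdr_vals <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  hdr <- setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- tolower(hdr[["Units"]])
  if (is.na(rate) || rate <= 0) stop("TRC header: invalid DataRate")
  if (!units %in% c("m", "mm"))
    stop(sprintf("TRC header: unsupported Units '%s' (need m or mm)", units))
  labels <- strsplit(lines[4L], "\t", fixed = TRUE)[[1L]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  if (length(labels) != n_markers)
    stop(sprintf("TRC header: %d marker labels but NumMarkers=%d",
                 length(labels), n_markers))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) != n_frames)
    stop(sprintf("TRC frame-count mismatch: header says %d frames, file has %d data rows",
                 n_frames, length(data_lines)))
  vals <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_expect <- 2L + 3L * n_markers
  nc <- lengths(vals)
  if (any(nc < ncol_expect))
    stop(sprintf("TRC parse error: data row %d has %d fields, expected %d (truncated file?)",
                 which(nc < ncol_expect)[1L], nc[nc < ncol_expect][1L], ncol_expect))
  mat <- matrix(as.numeric(unlist(lapply(vals, `[`, seq_len(ncol_expect)))),
                nrow = length(vals), byrow = TRUE)
  if (anyNA(mat)) stop("TRC parse error: non-numeric data field")
  scale <- if (units == "mm") 1e-3 else 1
  canon <- normalize_marker_names(labels, aliases)
  markers <- setNames(vector("list", n_markers), canon)
  for (j in seq_len(n_markers)) {
    markers[[j]] <- mat[, 2L + (3L * (j - 1L) + 1L):(3L * j), drop = FALSE] * scale
  }
  rec <- trial_recording(markers, rate)
  if (required) check_required_markers(rec)
  rec
}

#' Write marker trajectories as CSV
#'
#' Wide layout: commented header lines carrying the sampling rate and
#' metadata, then columns `frame`, `time`, and `<MARKER>.X/.Y/.Z` in
#' meters.
#'
#' @param recording a [trial_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csv_trajectories <- function(recording, path) {
  stopifnot(inherits(recording, "trial_recording"))
  if (!length(recording$markers) || recording$n_frames < 1L)
    stop("cannot write an empty recording")
  nm <- names(recording$markers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# turngait trajectory CSV (units: m, s)",
               sprintf("# sampling_rate: %s", fmt17(recording$sampling_rate))),
             con)
  md <- recording$metadata
  for (key in names(md)) {
    if (is.atomic(md[[key]]) && length(md[[key]]) == 1L)
      writeLines(sprintf("# meta %s: %s", key, format(md[[key]])), con)
  }
  coords <- do.call(cbind, recording$markers)
  colnames(coords) <- paste0(rep(nm, each = 3L), ".", c("X", "Y", "Z"))
  df <- data.frame(frame = seq_len(recording$n_frames) - 1L,
                   time = sprintf("%.6f", recording_time(recording)),
                   apply(coords, 2L, fmt17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  invisible(path)
}

#' Read marker trajectories from CSV
#'
#' Inverse of [write_csv_trajectories()]; the `# sampling_rate:` header
#' comment is required.
#'
#' @param path CSV path.
#' @param aliases alias map as [default_marker_aliases()].
#' @param required require the eight canonical markers (default `TRUE`).
#' @return a [trial_recording()].
#' @export
read_csv_trajectories <- function(path, aliases = default_marker_aliases(),
                                  required = TRUE) {
  lines <- readLines(path, warn = FALSE)
  cmt <- lines[startsWith(lines, "#")]
  rate_line <- grep("^#\\s*sampling_rate:", cmt, value = TRUE)
  if (!length(rate_line))
    stop("trajectory CSV schema violation: missing '# sampling_rate:' header")
  rate <- as.numeric(sub("^#\\s*sampling_rate:\\s*", "", rate_line[1L]))
  if (is.na(rate) || rate <= 0) stop("trajectory CSV: invalid sampling rate")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("trajectory CSV schema violation: no data rows")
  df <- read.csv(text = paste(body, collapse = "\n"), check.names = FALSE)
  cn <- colnames(df)
  if (!all(c("frame", "time") %in% cn))
    stop("trajectory CSV schema violation: need 'frame' and 'time' columns")
  coord_cols <- grep("\\.(X|Y|Z)$", cn, value = TRUE)
  if (!length(coord_cols) || length(coord_cols) %% 3L != 0L)
    stop("trajectory CSV schema violation: marker columns must come as X/Y/Z triplets")
  mk <- unique(sub("\\.(X|Y|Z)$", "", coord_cols))
  markers <- list()
  for (m in mk) {
    need <- paste0(m, ".", c("X", "Y", "Z"))
    if (!all(need %in% cn))
      stop(sprintf("trajectory CSV schema violation: incomplete triplet for marker %s", m))
    markers[[m]] <- as.matrix(df[, need])
  }
  names(markers) <- normalize_marker_names(names(markers), aliases)
  md <- list()
  meta_lines <- grep("^#\\s*meta\\s", cmt, value = TRUE)
  for (ml in meta_lines) {
    kv <- sub("^#\\s*meta\\s+", "", ml)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    md[[key]] <- if (!is.na(num)) num else val
  }
  rec <- trial_recording(markers, rate, metadata = md)
  if (required) check_required_markers(rec)
  rec
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth a `gait_ground_truth` from [generate_trial()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "gait_ground_truth"))
  payload <- list(events = truth$events, footfalls = truth$footfalls,
                  nominal = truth$nominal,
                  scenario = unclass(truth$scenario))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path JSON path written by [write_ground_truth()].
#' @return a `gait_ground_truth`.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(gait_scenario, x$scenario[setdiff(names(x$scenario), character(0))])
  structure(list(events = as.data.frame(x$events),
                 footfalls = as.data.frame(x$footfalls),
                 nominal = as.list(x$nominal), scenario = sc),
            class = "gait_ground_truth")
}

#' Write a parameter-by-condition results table
#'
#' One row per parameter in the canonical order ([PARAMETER_ORDER]),
#' with `mean`, `ci_low`, `ci_high` columns per condition -- the layout
#' of a condition-summary table (mean and bootstrap 95% CI across
#' subjects).
#'
#' @param results data.frame with columns `parameter`, `speed`,
#'   `amplitude`, `mean`, `ci_low`, `ci_high` (long format, e.g. from
#'   [condition_table()]).
#' @param path output CSV path.
#' @return the wide data.frame that was written, invisibly.
#' @export
write_results_table <- function(results, path) {
  need <- c("parameter", "speed", "amplitude", "mean", "ci_low", "ci_high")
  if (!all(need %in% colnames(results)))
    stop("`results` must have columns ", paste(need, collapse = ", "))
  conds <- unique(results[, c("speed", "amplitude")])
  conds <- conds[order(conds$speed, conds$amplitude), , drop = FALSE]
  pars <- intersect(PARAMETER_ORDER, unique(results$parameter))
  pars <- c(pars, setdiff(unique(results$parameter), pars))
  wide <- data.frame(parameter = pars, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(conds))) {
    tag <- sprintf("%s_%g", conds$speed[i], conds$amplitude[i])
    sub <- results[results$speed == conds$speed[i] &
                     results$amplitude == conds$amplitude[i], ]
    m <- match(pars, sub$parameter)
    wide[[paste0(tag, "_mean")]] <- sub$mean[m]
    wide[[paste0(tag, "_ci_low")]] <- sub$ci_low[m]
    wide[[paste0(tag, "_ci_high")]] <- sub$ci_high[m]
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(wide)
}
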
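# Shared data model, canonical CSV formats, trial validation.

#' Step geometry of the surface height change
#'
#' Describes the step-up box whose front rising edge defines the crossing
#' plane.  Defaults match the study apparatus: a 0.61 m wide, 0.075 m high,
#' 0.61 m deep box.
#'
#' @param edge_x anterior-posterior position of the front rising edge (m,
#'   lab frame).
#' @param height step height above the floor (m); must be > 0.
#' @param width medial-lateral extent (m); must be > 0.
#' @param depth anterior-posterior extent (m); must be > 0.
#' @return An object of class `step_geometry`.
#' @export
#' @examples
#' step_geometry(edge_x = 4.0)
step_geometry <- function(edge_x, height = 0.075, width = 0.61, depth = 0.61) {
  stopifnot(is.numeric(edge_x), length(edge_x) == 1L, is.finite(edge_x))
  if (height <= 0 || width <= 0 || depth <= 0)
    stop("step_geometry: height, width and depth must all be > 0")
  structure(list(edge_x = edge_x, height = height,
                 width = width, depth = depth),
            class = "step_geometry")
}

#' Marker trajectory
#'
#' A single labelled marker sampled at a fixed rate.  Positions are metres in
#' the package's lab frame (x anterior, y medial-lateral, z up).  Missing
#' samples are `NA` rows.
#'
#' @param name marker label.
#' @param xyz numeric matrix with columns `x`, `y`, `z` (one row per frame).
#' @param rate sampling frequency in Hz (100 Hz for study-conformant data).
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(name, xyz, rate = 100) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("marker_trajectory: xyz must have 3 columns")
  colnames(xyz) <- c("x", "y", "z")
  stopifnot(is.numeric(rate), rate > 0)
  structure(list(name = as.character(name), xyz = xyz, rate = rate),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s: %d frames @ %g Hz (%.2f s)\n",
              x$name, nrow(x$xyz), x$rate, (nrow(x$xyz) - 1L) / x$rate))
  invisible(x)
}

#' Frame times of a marker trajectory or gaze stream
#'
#' @param obj a `marker_trajectory` or `gaze_stream`.
#' @return numeric vector of sample times (s), 0-based frames.
#' @export
frame_times <- function(obj) {
  n <- if (inherits(obj, "gaze_stream")) length(obj$labels) else nrow(obj$xyz)
  (seq_len(n) - 1L) / obj$rate
}

#' Gaze stream of AOI-labelled samples
#'
#' @param labels character vector of AOI labels, one per frame; each must be
#'   one of `phone`, `travel_path`, `surface_height_change`, `other`,
#'   `untracked`.
#' @param rate sampling frequency in Hz (30 Hz for study-conformant data).
#' @return An object of class `gaze_stream`.
#' @export
gaze_stream <- function(labels, rate = 30) {
  labels <- as.character(labels)
  bad <- which(!(labels %in% AOI_LEVELS))
  if (length(bad))
    stop(sprintf("gaze_stream: unknown AOI label(s) %s at row(s) %s",
                 paste(unique(labels[bad]), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", ")))
  structure(list(labels = labels, rate = rate), class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples @ %g Hz (%.2f s), %.1f%% tracked\n",
              length(x$labels), x$rate, length(x$labels) / x$rate,
              100 * mean(x$labels != "untracked")))
  invisible(x)
}

#' Bundle of one trial's data
#'
#' @param participant_id participant identifier.
#' @param condition phone condition; one of `no_phone`, `talk`, `read`,
#'   `write`.
#' @param repetition repetition number (1-3 in the study design).
#' @param markers named list of [marker_trajectory()] objects sharing rate and
#'   length.
#' @param step a [step_geometry()].
#' @param gaze optional [gaze_stream()].
#' @param trial_duration trial duration in seconds; default inferred from the
#'   marker data.
#' @param calibration list of calibration info: `head_pitch` reference pitch
#'   in degrees (0 = straight ahead) and `gaze_ok` logical flag for good
#'   pre/post eye-tracker calibration.
#' @return An object of class `trial_bundle`.
#' @export
trial_bundle <- function(participant_id, condition, repetition, markers,
                         step, gaze = NULL, trial_duration = NULL,
                         calibration = list(head_pitch = 0, gaze_ok = TRUE)) {
  if (!condition %in% PHONE_CONDITIONS)
    stop(sprintf("trial_bundle: condition must be one of %s",
                 paste(PHONE_CONDITIONS, collapse = ", ")))
  stopifnot(is.list(markers), length(markers) > 0L)
  if (is.null(names(markers)) || any(names(markers) == ""))
    names(markers) <- vapply(markers, function(m) m$name, character(1))
  if (is.null(trial_duration)) {
    m1 <- markers[[1L]]
    trial_duration <- (nrow(m1$xyz) - 1L) / m1$rate
  }
  if (trial_duration <= 0) stop("trial_bundle: trial_duration must be > 0")
  structure(list(participant_id = participant_id, condition = condition,
                 repetition = as.integer(repetition), markers = markers,
                 gaze = gaze, step = step, trial_duration = trial_duration,
                 calibration = calibration),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf(
    "<trial_bundle> participant %s, %s, rep %d: %d markers, %s, %.2f s\n",
    x$participant_id, x$condition, x$repetition, length(x$markers),
    if (is.null(x$gaze)) "no gaze" else "gaze", x$trial_duration))
  invisible(x)
}

# ---- canonical CSV formats ------------------------------------------------

#' Write marker trajectories to the canonical CSV format
#'
#' Columns are `time, <marker>_x, <marker>_y, <marker>_z` in seconds/metres.
#' Missing samples become empty cells.
#'
#' @param markers named list of [marker_trajectory()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  stopifnot(length(markers) > 0L)
  rates <- vapply(markers, function(m) m$rate, numeric(1))
  lens <- vapply(markers, function(m) nrow(m$xyz), integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L)
    stop("write_marker_csv: markers must share rate and length")
  df <- data.frame(time = frame_times(markers[[1L]]))
  for (m in markers) {
    df[[paste0(m$name, "_x")]] <- m$xyz[, 1L]
    df[[paste0(m$name, "_y")]] <- m$xyz[, 2L]
    df[[paste0(m$name, "_z")]] <- m$xyz[, 3L]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read marker trajectories from the canonical CSV format
#'
#' The sampling rate is inferred from the `time` column, which must be
#' uniform and strictly increasing.
#'
#' @param path CSV file with columns `time, <marker>_x, <marker>_y,
#'   <marker>_z`.
#' @return named list of [marker_trajectory()] objects.
#' @export
read_marker_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_marker_csv: no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm))
    stop(sprintf("read_marker_csv: duplicate column(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (!"time" %in% nm) stop("read_marker_csv: missing 'time' column")
  tt <- df$time
  if (length(tt) < 2L) stop("read_marker_csv: need at least 2 frames")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("read_marker_csv: non-monotonic time column")
  if (max(abs(dt - mean(dt))) > 1e-6)
    stop("read_marker_csv: non-uniform sampling in time column")
  rate <- 1 / mean(dt)
  axcols <- grep("_[xyz]$", nm, value = TRUE)
  base <- unique(sub("_[xyz]$", "", axcols))
  out <- list()
  for (b in base) {
    need <- paste0(b, "_", c("x", "y", "z"))
    if (!all(need %in% nm))
      stop(sprintf("read_marker_csv: incomplete axis columns for marker %s", b))
    out[[b]] <- marker_trajectory(b, cbind(df[[need[1]]], df[[need[2]]],
                                           df[[need[3]]]), rate = rate)
  }
  if (!length(out)) stop("read_marker_csv: no marker columns found")
  out
}

#' Write a gaze stream to the canonical CSV format (`time, aoi`)
#'
#' @param stream a [gaze_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(stream, path) {
  utils::write.csv(data.frame(time = frame_times(stream),
                              aoi = stream$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a gaze stream from the canonical CSV format
#'
#' @param path CSV file with columns `time, aoi`; one AOI label per row, from
#'   the closed label set.
#' @return a [gaze_stream()].
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_gaze_csv: no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("time", "aoi") %in% names(df)))
    stop("read_gaze_csv: need columns 'time' and 'aoi'")
  bad <- which(!(df$aoi %in% AOI_LEVELS))
  if (length(bad))
    stop(sprintf("read_gaze_csv: unknown AOI label(s) %s at row(s) %s",
                 paste(unique(df$aoi[bad]), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", ")))
  rate <- if (nrow(df) >= 2L) 1 / mean(diff(df$time)) else 30
  gaze_stream(df$aoi, rate = rate)
}

# ---- flat YAML subset for trial metadata / axis maps ----------------------

#' Read a flat YAML-subset file
#'
#' Supports the small subset of YAML used for trial metadata and axis maps:
#' `key: value` scalars and one level of nested maps introduced by `key:` and
#' two-space indentation.  Numbers are converted; everything else stays
#' character.  Comments (`#`) and blank lines are ignored.
#'
#' @param path file to read.
#' @return nested named list.
#' @export
read_yaml_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  out <- list()
  current <- NULL  # name of open nested map
  for (ln in lines) {
    indented <- grepl("^\\s+", ln)
    body <- trimws(ln)
    m <- regmatches(body, regexec("^([A-Za-z0-9_.-]+):\\s*(.*)$", body))[[1L]]
    if (length(m) != 3L) stop(sprintf("read_yaml_flat: cannot parse line: %s", ln))
    key <- m[2L]; val <- m[3L]
    conv <- function(v) {
      v <- gsub("^['\"]|['\"]$", "", v)
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }
    if (!indented && val == "") {
      current <- key
      out[[current]] <- list()
    } else if (indented) {
      if (is.null(current)) stop("read_yaml_flat: indentation without a parent key")
      out[[current]][[key]] <- conv(val)
    } else {
      current <- NULL
      out[[key]] <- conv(val)
    }
  }
  out
}

#' Read trial metadata (participant, condition, repetition, step, rates)
#'
#' @param path YAML-subset file with keys `participant`, `condition`,
#'   `repetition`, optional `marker_rate`/`gaze_rate`, and a nested `step:`
#'   map with `edge_x`, `height`, `width`, `depth`.
#' @return list with parsed fields; `step` is a [step_geometry()].
#' @export
read_trial_meta <- function(path) {
  y <- read_yaml_flat(path)
  if (!is.null(y$step)) {
    s <- y$step
    y$step <- step_geometry(edge_x = s$edge_x,
                            height = if (is.null(s$height)) 0.075 else s$height,
                            width = if (is.null(s$width)) 0.61 else s$width,
                            depth = if (is.null(s$depth)) 0.61 else s$depth)
  }
  y
}

# ---- validation -----------------------------------------------------------

#' Validate a trial bundle
#'
#' Pure check returning human-readable findings; an empty character vector
#' means all invariants hold.  With `strict = TRUE` the study-conformant
#' rates (100 Hz markers, 30 Hz gaze) are enforced.
#'
#' @param bundle a [trial_bundle()].
#' @param required_markers marker labels that must be present (default: the
#'   full study marker set).
#' @param strict enforce study-conformant sampling rates.
#' @return character vector of findings (empty if valid).
#' @export
validate_trial <- function(bundle, required_markers = MARKER_SET,
                           strict = TRUE) {
  findings <- character(0)
  if (!inherits(bundle, "trial_bundle"))
    return("not a trial_bundle object")
  miss <- setdiff(required_markers, names(bundle$markers))
  for (m in miss) findings <- c(findings, sprintf("marker %s absent", m))
  rates <- vapply(bundle$markers, function(m) m$rate, numeric(1))
  lens <- vapply(bundle$markers, function(m) nrow(m$xyz), integer(1))
  if (length(unique(rates)) > 1L)
    findings <- c(findings, "marker trajectories do not share a sampling rate")
  if (length(unique(lens)) > 1L)
    findings <- c(findings, "marker trajectories do not share a length")
  if (strict && length(unique(rates)) == 1L && abs(rates[1L] - 100) > 1e-9)
    findings <- c(findings,
                  sprintf("marker rate %g Hz differs from 100 Hz", rates[1L]))
  if (!inherits(bundle$step, "step_geometry"))
    findings <- c(findings, "step geometry absent")
  if (!is.null(bundle$gaze) && strict && abs(bundle$gaze$rate - 30) > 1e-9)
    findings <- c(findings,
                  sprintf("gaze rate %g Hz differs from 30 Hz", bundle$gaze$rate))
  if (bundle$trial_duration <= 0)
    findings <- c(findings, "trial duration must be > 0")
  findings
}

#' Interpolate short gaps in a marker trajectory
#'
#' Linear interpolation of missing samples for gaps of at most `max_gap`
#' frames (100 ms at 100 Hz); longer gaps are left as `NA` so that dependent
#' variables can be flagged.
#'
#' @param traj a [marker_trajectory()].
#' @param max_gap maximum gap length (frames) that may be bridged.
#' @return a [marker_trajectory()] with short gaps filled.
#' @export
interpolate_gaps <- function(traj, max_gap = 10L) {
  xyz <- traj$xyz
  n <- nrow(xyz)
  miss <- rowSums(is.na(xyz)) > 0
  if (!any(miss)) return(traj)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1L; i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > n) next  # gap touches a boundary: leave missing
    idx <- starts[k]:ends[k]
    for (j in 1:3) {
      xyz[idx, j] <- xyz[i0, j] +
        (xyz[i1, j] - xyz[i0, j]) * (idx - i0) / (i1 - i0)
    }
  }
  marker_trajectory(traj$name, xyz, traj$rate)
}
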
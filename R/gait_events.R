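# Gait event detection: foot contacts, lead/trail assignment, edge crossing.

# Height of the supporting surface under anterior-posterior position x.
support_height <- function(x, step) {
  ifelse(x >= step$edge_x & x <= step$edge_x + step$depth, step$height, 0)
}

#' Detect foot contacts (stance intervals) from toe and heel markers
#'
#' Coordinate-based detection: frames where the toe marker's 3-D speed is
#' below `speed_threshold` and its height is within `height_threshold` of the
#' supporting surface (floor, or step top between the front and back edges)
#' are stance candidates; runs of at least `min_stance` seconds become stance
#' intervals.  The representative contact time is the first frame of the
#' interval; the planted position is the median over the interval.
#'
#' @param toe,heel filtered [marker_trajectory()] objects for one foot.
#' @param step a [step_geometry()].
#' @param speed_threshold stance speed threshold (m/s).
#' @param height_threshold allowed height above the support surface (m).
#' @param min_stance minimum stance duration (s).
#' @return data.frame with one row per stance: `start_time`, `end_time`,
#'   `contact_time`, `toe_x`, `heel_x`, `y`, `z`, `surface` ("floor" or
#'   "step").
#' @export
detect_foot_contacts <- function(toe, heel, step,
                                 speed_threshold = 0.2,
                                 height_threshold = 0.015,
                                 min_stance = 0.1) {
  rate <- toe$rate
  v <- cbind(central_diff(toe$xyz[, 1], rate),
             central_diff(toe$xyz[, 2], rate),
             central_diff(toe$xyz[, 3], rate))
  speed <- sqrt(rowSums(v^2))
  surf <- support_height(toe$xyz[, 1], step)
  on_surface <- abs(toe$xyz[, 3] - surf) < height_threshold
  stance <- speed < speed_threshold & on_surface
  stance[is.na(stance)] <- FALSE
  r <- rle(stance)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= max(2L, round(min_stance * rate)))
  if (!length(keep))
    stop("detect_foot_contacts: no stance interval found; trial flagged")
  # refine contact instants at the upward crossing of the vertical velocity
  # through half a typical foot-fall descent speed: the crossing stays
  # centred on the contact under zero-phase smoothing of the velocity step
  vz <- v[, 3]
  az <- central_diff(vz, rate)
  refine <- function(s) {
    if (s <= 2L) return((s - 1L) / rate)
    lo <- max(2L, s - 8L); hi <- min(length(vz) - 1L, s + 1L)
    cross <- which(vz[lo:hi] <= -0.2 & vz[(lo + 1L):(hi + 1L)] > -0.2)
    if (length(cross)) {
      i <- lo + cross[length(cross)] - 1L
      frac <- (-0.2 - vz[i]) / (vz[i + 1L] - vz[i])
      return((i - 1L + frac) / rate)
    }
    win <- lo:hi                       # fallback: vertical impact peak
    (win[which.max(az[win])] - 1L) / rate
  }
  rows <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    tx <- stats::median(toe$xyz[idx, 1])
    data.frame(start_time = (starts[k] - 1L) / rate,
               end_time = (ends[k] - 1L) / rate,
               contact_time = refine(starts[k]),
               toe_x = tx,
               heel_x = stats::median(heel$xyz[idx, 1]),
               y = stats::median(toe$xyz[idx, 2]),
               z = stats::median(toe$xyz[idx, 3]),
               surface = if (support_height(tx, step) > 0) "step" else "floor")
  })
  do.call(rbind, rows)
}

#' Assign lead/trail limbs and label the key gait events
#'
#' The lead foot is the first foot to contact the ground beyond the step's
#' front rising edge; the trail foot is the other.  The penultimate and final
#' floor contacts are the last two stances with positions short of the edge.
#'
#' @param contacts_left,contacts_right stance tables from
#'   [detect_foot_contacts()] for the left and right foot.
#' @param step a [step_geometry()].
#' @return list of class `gait_events`: `lead`, `trail` ("left"/"right"),
#'   `penultimate` / `final` / `lead_landing` / `trail_landing` (one-row
#'   stance records), and event times.
#' @export
assign_lead_trail <- function(contacts_left, contacts_right, step) {
  contacts_left$foot <- "left"; contacts_right$foot <- "right"
  all_c <- rbind(contacts_left, contacts_right)
  all_c <- all_c[order(all_c$contact_time), , drop = FALSE]
  beyond <- all_c[all_c$toe_x > step$edge_x, , drop = FALSE]
  if (!nrow(beyond))
    stop("assign_lead_trail: no contact beyond the edge (step not negotiated)")
  lead <- beyond$foot[1L]
  trail <- setdiff(c("left", "right"), lead)
  lead_landing <- beyond[1L, , drop = FALSE]
  trail_beyond <- beyond[beyond$foot == trail, , drop = FALSE]
  if (!nrow(trail_beyond))
    stop("assign_lead_trail: trail foot never lands beyond the edge")
  trail_landing <- trail_beyond[1L, , drop = FALSE]
  floor_c <- all_c[all_c$toe_x < step$edge_x &
                     all_c$contact_time < lead_landing$contact_time, ,
                   drop = FALSE]
  if (nrow(floor_c) < 2L)
    stop("assign_lead_trail: fewer than two floor contacts before the edge")
  final <- floor_c[nrow(floor_c), , drop = FALSE]
  penult <- floor_c[nrow(floor_c) - 1L, , drop = FALSE]
  structure(list(lead = lead, trail = trail,
                 penultimate = penult, final = final,
                 lead_landing = lead_landing, trail_landing = trail_landing,
                 t_penultimate = penult$contact_time,
                 t_final = final$contact_time,
                 t_lead_landing = lead_landing$contact_time,
                 t_trail_landing = trail_landing$contact_time),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf(paste0("<gait_events> lead=%s trail=%s | penult %.2fs, ",
                     "final %.2fs, lead land %.2fs, trail land %.2fs\n"),
              x$lead, x$trail, x$t_penultimate, x$t_final,
              x$t_lead_landing, x$t_trail_landing))
  invisible(x)
}

#' Sub-frame instant at which the toe crosses the rising edge
#'
#' Linear interpolation between the last frame with `x < edge_x` and the
#' first frame with `x >= edge_x` inside the swing window.  If the crossing
#' falls exactly on a frame, that frame's time is returned.
#'
#' @param toe a [marker_trajectory()].
#' @param edge_x anterior-posterior position of the front rising edge (m).
#' @param window optional `c(t0, t1)` restricting the search to the swing
#'   phase.
#' @return crossing time (s).
#' @export
crossing_instant <- function(toe, edge_x, window = NULL) {
  x <- toe$xyz[, 1]
  tt <- frame_times(toe)
  ok <- if (is.null(window)) rep(TRUE, length(x)) else
    tt >= window[1] & tt <= window[2]
  idx <- which(ok & x < edge_x & c(x[-1], NA) >= edge_x)
  if (!length(idx)) {
    # crossing may fall exactly on the first in-window frame
    exact <- which(ok & x == edge_x)
    if (length(exact)) return(tt[exact[1L]])
    stop("crossing_instant: toe does not cross the edge inside the window")
  }
  i <- idx[length(idx)]
  frac <- (edge_x - x[i]) / (x[i + 1L] - x[i])
  tt[i] + frac / toe$rate
}

#' Vertical toe clearance at the crossing instant
#'
#' Toe height above the step's upper front edge when the toe passes the edge
#' plane, in millimetres.  Negative values mean the toe passed below the edge
#' plane and are flagged as virtual contact.
#'
#' @param toe a [marker_trajectory()].
#' @param crossing_time crossing instant from [crossing_instant()].
#' @param step a [step_geometry()].
#' @return clearance in mm with attribute `virtual_contact` (logical).
#' @export
toe_clearance <- function(toe, crossing_time, step) {
  z <- interp_at(toe$xyz[, 3], toe$rate, crossing_time)
  cl <- (z - step$height) * 1000
  attr(cl, "virtual_contact") <- cl < 0
  cl
}

#' Horizontal toe velocity at the crossing instant
#'
#' Anterior-posterior toe velocity from central differences of the filtered
#' x trajectory, linearly interpolated at the crossing instant.
#'
#' @param toe a [marker_trajectory()] (already filtered).
#' @param crossing_time crossing instant (s).
#' @return velocity in m/s.
#' @export
horizontal_toe_velocity <- function(toe, crossing_time) {
  n <- nrow(toe$xyz)
  if (crossing_time < 2 / toe$rate ||
      crossing_time > (n - 3L) / toe$rate)
    stop("horizontal_toe_velocity: crossing within 2 frames of trial boundary")
  vx <- central_diff(toe$xyz[, 1], toe$rate)
  interp_at(vx, toe$rate, crossing_time)
}
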
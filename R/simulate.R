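# Synthetic trial generator: parametric stride sequences, constrained swing
# arcs, head-pitch series, sternum sway and semi-structured gaze streams,
# all with recorded ground truth.

# minimum-jerk position profile and helpers
minjerk_s <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
minjerk_sp <- function(tau) 30 * tau^2 * (1 - tau)^2
minjerk_inv <- function(s_target) {
  stopifnot(s_target > 0, s_target < 1)
  stats::uniroot(function(t) minjerk_s(t) - s_target, c(1e-9, 1 - 1e-9),
                 tol = 1e-12)$root
}

# piecewise cubic Hermite through (t, value, slope) knots
hermite_eval <- function(tq, kt, kv, km) {
  n <- length(kt)
  out <- numeric(length(tq))
  seg <- findInterval(tq, kt, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L; seg[seg >= n] <- n - 1L
  h <- kt[seg + 1L] - kt[seg]
  u <- (tq - kt[seg]) / h
  u <- pmin(pmax(u, 0), 1)
  out <- kv[seg] * (2 * u^3 - 3 * u^2 + 1) +
    h * km[seg] * (u^3 - 2 * u^2 + u) +
    kv[seg + 1L] * (-2 * u^3 + 3 * u^2) +
    h * km[seg + 1L] * (u^3 - u^2)
  out
}

# landing descent speed (m/s) used for every swing; a physiological foot-fall
# velocity that also makes threshold-based contact detection symmetric under
# zero-phase filtering (see methods vignette)
.V_LAND <- 0.4

# Draw one trial's target parameter set from a preset (+ optional additive
# participant offsets), with feasibility clamps.  sd_scale = 0 gives the
# preset means exactly.
draw_trial_params <- function(preset, sd_scale = 1, offsets = NULL) {
  draw <- function(name, lo = -Inf, hi = Inf) {
    v <- preset[[name]]
    if (is.na(v["mean"])) return(NA_real_)
    off <- if (!is.null(offsets) && !is.null(offsets[[name]]))
      offsets[[name]] else 0
    val <- v["mean"] + off + sd_scale * v["sd"] * stats::rnorm(1L)
    min(max(unname(val), lo), hi)
  }
  p <- list(
    trial_time = draw("trial_time", lo = 3.2, hi = 25),
    lead_stride = draw("lead_stride", lo = 0.45, hi = 1.8),
    trail_stride = draw("trail_stride", lo = 0.45, hi = 1.8),
    lead_clearance = draw("lead_clearance", lo = 15, hi = 320),
    trail_clearance = draw("trail_clearance", lo = 15, hi = 320),
    lead_velocity = draw("lead_velocity", lo = 0.6, hi = 6),
    trail_velocity = draw("trail_velocity", lo = 0.6, hi = 6),
    lead_post = draw("lead_post", lo = 0.08, hi = 0.55),
    trail_post = draw("trail_post", lo = 0.12, hi = 1.4),
    bve = draw("bve", lo = 0.01, hi = 3),
    head = c(penultimate_contact = draw("head_penultimate"),
             final_contact = draw("head_final"),
             lead_crossing = draw("head_crossing"),
             lead_contact_after = draw("head_lead_after"),
             trail_contact_after = draw("head_trail_after")),
    gaze_count = c(phone = draw("count_phone", 0, 100),
                   surface_height_change = draw("count_shc", 0, 100),
                   travel_path = draw("count_path", 0, 100),
                   other = draw("count_other", 0, 100)),
    gaze_time = c(phone = draw("time_phone", 0, 100),
                  surface_height_change = draw("time_shc", 0, 100),
                  travel_path = draw("time_path", 0, 100),
                  other = draw("time_other", 0, 100)),
    condition = preset$condition,
    present_aois = preset$present_aois
  )
  # derived pre-edge placements; enforce a feasible footfall geometry
  p$lead_pre <- p$lead_stride - p$lead_post
  p$trail_pre <- p$trail_stride - p$trail_post
  if (p$trail_pre < 0.08) {
    p$trail_pre <- 0.08
    p$trail_post <- p$trail_stride - p$trail_pre
  }
  if (p$lead_pre < p$trail_pre + 0.12) {
    p$lead_pre <- p$trail_pre + 0.12
    p$lead_stride <- p$lead_pre + p$lead_post
  }
  # renormalise gaze targets
  pres <- p$present_aois
  cs <- sum(p$gaze_count[pres])
  if (is.finite(cs) && cs > 0) p$gaze_count[pres] <- p$gaze_count[pres] / cs * 100
  ts <- sum(p$gaze_time[pres])
  if (is.finite(ts) && ts > 96) p$gaze_time[pres] <- p$gaze_time[pres] / ts * 96
  p
}

# crossing-swing geometry: duration and crossing phase from the velocity
# constraint at the rising edge
crossing_swing <- function(x0, x1, edge_x, v_cross) {
  dx <- x1 - x0
  s_star <- (edge_x - x0) / dx
  if (s_star <= 0.02 || s_star >= 0.98)
    stop("simulate_trial: infeasible crossing geometry")
  tau_star <- minjerk_inv(s_star)
  D <- dx * minjerk_sp(tau_star) / v_cross
  list(duration = D, tau_star = tau_star)
}

# A crossing too close to toe-off or landing implies unphysical foot
# accelerations (and biases any band-limited measurement).  Repair
# degenerate draws by adjusting the footfall geometry until the swing lasts
# at least `min_D` seconds with at least `min_phase` seconds on either side
# of the edge crossing.
adjust_crossing <- function(pre, post, v_cross, edge_x, post_max,
                            drop = 0.1, min_D = 0.35, min_phase = 0.14) {
  # the descent from the crossing apex cannot be faster than gravity allows
  min_fall <- max(min_phase, sqrt(2 * max(drop, 0.02) / 9.81) + 0.05)
  for (i in 1:60) {
    cr <- crossing_swing(edge_x - pre, edge_x + post, edge_x, v_cross)
    t_rise <- cr$tau_star * cr$duration
    t_fall <- (1 - cr$tau_star) * cr$duration
    if (cr$duration >= min_D && t_rise >= min_phase && t_fall >= min_fall)
      break
    if (t_rise < min_phase && pre < 1.25) pre <- pre + 0.04
    else if (post + 0.04 <= post_max) post <- post + 0.04
    else if (pre > 0.35) pre <- pre - 0.05
    else break
  }
  list(pre = pre, post = post, cr = cr)
}

# head pitch cannot change faster than people rotate their heads mid-gait
rate_limit_head <- function(times, values, max_rate = 150) {
  for (i in 2:length(values)) {
    allowed <- max_rate * (times[i] - times[i - 1L])
    values[i] <- min(max(values[i], values[i - 1L] - allowed),
                     values[i - 1L] + allowed)
  }
  values
}

# z knots for one swing (times relative to swing start, slopes m/s).
# The crossing constraint is honoured on the smooth rising limb (matched
# slope, broad apex shortly after the edge) so that the profile carries
# little energy above the conventional 6 Hz analysis band.
swing_z_knots <- function(D, z0, z1, cross = NULL, step = NULL) {
  # constant-velocity touchdown pad: the last ~30 ms descend at the landing
  # speed, so the foot-fall velocity step is clean for event detection
  pad <- function(kt, kv, km, D, z1) {
    tp <- D - 0.03
    if (tp > kt[length(kt)] + 0.02)
      list(t = c(kt, tp, D), v = c(kv, z1 + .V_LAND * 0.03, z1),
           m = c(km, -.V_LAND, -.V_LAND))
    else list(t = c(kt, D), v = c(kv, z1), m = c(km, -.V_LAND))
  }
  if (is.null(cross)) {             # plain approach swing: 5 cm apex bump
    apex <- max(z0, z1) + 0.05
    return(pad(c(0, D / 2), c(z0, apex), c(0, 0), D, z1))
  }
  t_star <- cross$tau_star * D
  z_star <- step$height + cross$clearance_m
  m_star <- 1.15 * (z_star - z0) / t_star       # just above the secant slope
  t_exit <- if (!is.null(cross$tau_exit)) cross$tau_exit * D else NA_real_
  t_apex <- if (is.finite(t_exit) && t_exit < D - 0.05)
    t_star + 0.5 * (t_exit - t_star) else t_star + 0.5 * (D - t_star)
  t_apex <- min(max(t_apex, t_star + 0.06), D - 0.04)
  # a locally linear window around the crossing keeps the zero-phase filter
  # from biasing the measured clearance
  dz <- min(0.06, (t_apex - t_star) / 3.3, t_star / 3)
  z_apex <- z_star + m_star * max((t_apex - t_star) / 3, 1.1 * dz)
  kt <- c(0, t_star - dz, t_star + dz, t_apex)
  kv <- c(z0, z_star - m_star * dz, z_star + m_star * dz, z_apex)
  km <- c(0, m_star, m_star, 0)
  if (is.finite(t_exit) && t_exit > t_apex + 0.05 && t_exit < D - 0.06) {
    # trail foot landing beyond the box: stay high across the box span
    kt <- c(kt, t_exit)
    kv <- c(kv, max(step$height + 0.6 * cross$clearance_m, z1 + 0.02))
    km <- c(km, -0.2)
  }
  pad(kt, kv, km, D, z1)
}

# Build one foot's toe trajectory from its plant schedule.
# plants: data.frame(time, x, z, toeoff_before, swing list-col omitted) --
# implemented as lists for clarity.
build_foot <- function(tt, init_x, plan, step) {
  n <- length(tt)
  x <- rep(init_x, n); z <- numeric(n)
  prev_x <- init_x; prev_z <- 0
  for (seg in plan) {
    sw <- tt >= seg$t_off & tt < seg$t_land
    tau <- (tt[sw] - seg$t_off) / (seg$t_land - seg$t_off)
    if (is.null(seg$cross)) {
      x[sw] <- prev_x + (seg$x - prev_x) * minjerk_s(tau)
    } else {
      # crossing swing: Hermite profile with a constant-velocity window
      # around the edge so the filtered velocity equals the target exactly
      D <- seg$t_land - seg$t_off
      ts <- seg$cross$tau_star * D
      v <- seg$cross$v_cross
      edge <- seg$cross$edge_x
      dxw <- min(0.06, ts / 3, (D - ts) / 3)
      x[sw] <- hermite_eval(tt[sw] - seg$t_off,
                            c(0, ts - dxw, ts + dxw, D),
                            c(prev_x, edge - v * dxw, edge + v * dxw, seg$x),
                            c(0, v, v, 0))
    }
    kn <- swing_z_knots(seg$t_land - seg$t_off, prev_z, seg$z,
                        seg$cross, step)
    z[sw] <- hermite_eval(tt[sw] - seg$t_off, kn$t, kn$v, kn$m)
    after <- tt >= seg$t_land
    x[after] <- seg$x; z[after] <- seg$z
    prev_x <- seg$x; prev_z <- seg$z
  }
  list(x = x, z = z)
}

#' Simulate one trial with known ground truth
#'
#' Builds 100 Hz marker trajectories (parametric stride sequence with a
#' constrained crossing arc that attains the drawn toe clearance and
#' horizontal velocity at the rising edge), a head-pitch series through the
#' five event targets, sternum medial-lateral sway scaled to the drawn BVE,
#' and a 30 Hz gaze stream whose realised fixation-time fractions match the
#' drawn targets (counts match up to one-fixation granularity; see the
#' methods vignette).
#'
#' @param preset a [condition_presets()] object.
#' @param step a [step_geometry()], or `NULL` to draw the front edge
#'   uniformly in 3.95-4.05 m (the apparatus jitter).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param sd_scale multiplier on every preset SD (0 = all targets at the
#'   preset means).
#' @param marker_noise_sd additive Gaussian marker noise (m); the 0.5 mm
#'   default is representative of active-marker optoelectronic systems; set 0
#'   for noiseless recovery checks.
#' @param participant_id,repetition metadata passed into the bundle.
#' @param offsets optional named list of additive per-variable offsets
#'   (used by [simulate_cohort()] for between-participant variation).
#' @return list with `bundle` (a [trial_bundle()]) and `truth` (ground-truth
#'   record of every realised parameter, contact and crossing time).
#' @export
simulate_trial <- function(preset, step = NULL, seed = NULL, sd_scale = 1,
                           marker_noise_sd = 5e-4, participant_id = "P01",
                           repetition = 1L, offsets = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  if (is.null(step)) step <- step_geometry(edge_x = stats::runif(1, 3.95, 4.05))
  p <- draw_trial_params(preset, sd_scale, offsets)
  rate <- 100
  walkway <- 5.6
  if (step$edge_x + p$trail_post > walkway + 0.3)
    stop("simulate_trial: generation error: stride exceeds walkway")

  lead_side <- sample(c("left", "right"), 1L)
  trail_side <- setdiff(c("left", "right"), lead_side)

  adj_l <- adjust_crossing(p$lead_pre, p$lead_post, p$lead_velocity,
                           step$edge_x, post_max = step$depth - 0.03,
                           drop = p$lead_clearance / 1000)
  p$lead_pre <- adj_l$pre; p$lead_post <- adj_l$post
  p$lead_stride <- p$lead_pre + p$lead_post
  adj_t <- adjust_crossing(p$trail_pre, p$trail_post, p$trail_velocity,
                           step$edge_x, post_max = 1.45,
                           drop = step$height + p$trail_clearance / 1000)
  p$trail_pre <- adj_t$pre; p$trail_post <- adj_t$post
  p$trail_stride <- p$trail_pre + p$trail_post
  if (p$lead_pre < p$trail_pre + 0.12) {      # keep footfall ordering
    p$lead_pre <- p$trail_pre + 0.12
    p$lead_stride <- p$lead_pre + p$lead_post
    adj_l <- adjust_crossing(p$lead_pre, p$lead_post, p$lead_velocity,
                             step$edge_x, post_max = step$depth - 0.03,
                             drop = p$lead_clearance / 1000)
    p$lead_pre <- adj_l$pre; p$lead_post <- adj_l$post
    p$lead_stride <- p$lead_pre + p$lead_post
  }
  x_Lf <- step$edge_x - p$lead_pre     # lead final floor plant (penultimate)
  x_Tf <- step$edge_x - p$trail_pre    # trail final floor plant (final)

  cr_lead <- adj_l$cr
  cr_lead$clearance_m <- p$lead_clearance / 1000
  cr_lead$v_cross <- p$lead_velocity
  cr_lead$edge_x <- step$edge_x
  cr_trail <- adj_t$cr
  cr_trail$clearance_m <- p$trail_clearance / 1000
  cr_trail$v_cross <- p$trail_velocity
  cr_trail$edge_x <- step$edge_x
  cr_trail$tau_exit <- tryCatch(
    minjerk_inv(min((step$edge_x + step$depth - x_Tf) /
                      (p$trail_post + p$trail_pre), 0.999)),
    error = function(e) NULL)
  lead_land_z <- support_height(step$edge_x + p$lead_post, step)
  trail_land_z <- support_height(step$edge_x + p$trail_post, step)

  # approach footfalls (uniform spacing, ending at the lead final plant)
  t0 <- 0.35; gap <- 0.62; h_end <- 0.4; push_off <- 0.08
  repeat {
    K <- max(0L, floor((x_Lf - 0.45) / gap))
    m_floor <- K + 2L
    budget <- p$trial_time - t0 - 2 * push_off - cr_lead$duration -
      cr_trail$duration - h_end
    dt_step <- budget / m_floor
    if (dt_step >= 0.32 || gap > 1.1) break
    gap <- gap + 0.15                   # fewer, longer approach steps
  }
  # a drawn trial time can be infeasibly short for the drawn crossing swings
  # (slow crossing velocity => long swing); repair by walking at a brisk but
  # realistic cadence and letting the realised duration run over the draw
  if (dt_step < 0.32) dt_step <- 0.45
  app_x <- if (K > 0L) x_Lf - gap * (K:1) else numeric(0)
  floor_x <- c(app_x, x_Lf, x_Tf)
  floor_t <- t0 + seq_len(m_floor) * dt_step
  t_lead_off <- floor_t[m_floor] + push_off
  t_lead_land <- t_lead_off + cr_lead$duration
  t_trail_off <- t_lead_land + push_off
  t_trail_land <- t_trail_off + cr_trail$duration
  T_end <- t_trail_land + h_end
  nf <- max(2L, round(T_end * rate) + 1L)
  tt <- (seq_len(nf) - 1L) / rate

  # assign footfalls to feet: the lead foot takes floor footfall m_floor - 1
  foot_of <- rep(c("a", "b"), length.out = m_floor)
  side_of <- ifelse(foot_of == foot_of[m_floor - 1L], lead_side, trail_side)
  w_swing <- min(0.8 * dt_step, 0.7)
  plan <- list(left = list(), right = list())
  for (i in seq_len(m_floor)) {
    s <- side_of[i]
    plan[[s]][[length(plan[[s]]) + 1L]] <-
      list(t_off = floor_t[i] - w_swing, t_land = floor_t[i],
           x = floor_x[i], z = 0, cross = NULL)
  }
  plan[[lead_side]][[length(plan[[lead_side]]) + 1L]] <-
    list(t_off = t_lead_off, t_land = t_lead_land,
         x = step$edge_x + p$lead_post, z = lead_land_z, cross = cr_lead)
  plan[[trail_side]][[length(plan[[trail_side]]) + 1L]] <-
    list(t_off = t_trail_off, t_land = t_trail_land,
         x = step$edge_x + p$trail_post, z = trail_land_z, cross = cr_trail)

  init_x <- stats::setNames(c(0, 0.15), c(side_of[1L], side_of[2L]))
  feet <- list(
    left = build_foot(tt, max(plan$left[[1L]]$x - 2 * gap, init_x[["left"]]),
                      plan$left, step),
    right = build_foot(tt, max(plan$right[[1L]]$x - 2 * gap, init_x[["right"]]),
                       plan$right, step))

  # sternum: body progression + medial-lateral sway scaled to the BVE target
  st_x <- (feet$left$x + feet$right$x) / 2
  nwave <- 8L
  freqs <- stats::runif(nwave, 0.15, 0.9)
  phases <- stats::runif(nwave, 0, 2 * pi)
  amps <- stats::runif(nwave, 0.5, 1)
  st_y <- rowSums(sapply(seq_len(nwave), function(j)
    amps[j] * sin(2 * pi * freqs[j] * tt + phases[j])))
  st_y <- st_y - mean(st_y)
  st_y <- st_y * p$bve / sqrt(mean(st_y^2))

  # head pitch through the five event targets
  t_cross_lead <- t_lead_off + cr_lead$tau_star * cr_lead$duration
  t_cross_trail <- t_trail_off + cr_trail$tau_star * cr_trail$duration
  ev_t <- c(floor_t[m_floor - 1L], floor_t[m_floor], t_cross_lead,
            t_lead_land, t_trail_land)
  p$head[] <- rate_limit_head(ev_t, p$head)
  # short plateaus around each event: head pose is quasi-stable at the gait
  # events, which also makes the realised pitch robust to event-timing jitter
  kn_t <- 0; kn_v <- p$head[1L]
  gaps <- diff(c(0, ev_t, T_end))
  for (i in seq_along(ev_t)) {
    wl <- min(0.05, gaps[i] / 3); wr <- min(0.05, gaps[i + 1L] / 3)
    kn_t <- c(kn_t, ev_t[i] - wl, ev_t[i] + wr)
    kn_v <- c(kn_v, p$head[i], p$head[i])
  }
  kn_t <- c(kn_t, T_end); kn_v <- c(kn_v, p$head[5L])
  pitch_deg <- hermite_eval(tt, kn_t, kn_v, rep(0, length(kn_v)))
  theta <- pitch_deg * pi / 180
  head_center <- cbind(st_x + 0.05, 0, 1.62)
  rot_off <- function(dx, dy, dz)
    cbind(head_center[, 1] + dx * cos(theta) + dz * sin(theta),
          dy,
          head_center[, 3] - dx * sin(theta) + dz * cos(theta))

  mk <- list()
  for (s in c("left", "right")) {
    ys <- if (s == "left") 0.10 else -0.10
    f <- feet[[s]]
    mk[[paste0("toe_", s)]] <- cbind(f$x, ys, f$z)
    mk[[paste0("met_", s)]] <- cbind(f$x - 0.04, ys, f$z)
    mk[[paste0("heel_", s)]] <- cbind(f$x - 0.22, ys, f$z)
    mk[[paste0("mall_", s)]] <- cbind(f$x - 0.18, ys + 0.02, f$z + 0.07)
  }
  mk$sternum <- cbind(st_x, st_y, 1.35)
  mk$head_al_left <- rot_off(0.09, 0.075, 0.02)
  mk$head_al_right <- rot_off(0.09, -0.075, 0.02)
  mk$head_pl_left <- rot_off(-0.09, 0.075, 0.02)
  mk$head_pl_right <- rot_off(-0.09, -0.075, 0.02)
  markers <- lapply(names(mk), function(nm) {
    xyz <- mk[[nm]]
    if (marker_noise_sd > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, marker_noise_sd),
                          nrow = nrow(xyz))
    marker_trajectory(nm, xyz, rate)
  })
  names(markers) <- names(mk)

  gaze <- simulate_gaze_stream(T_end, p$gaze_count, p$gaze_time,
                               p$present_aois)

  bundle <- trial_bundle(participant_id, p$condition, repetition, markers,
                         step, gaze = gaze$stream,
                         calibration = list(head_pitch = 0, gaze_ok = TRUE))
  truth <- list(
    condition = p$condition, trial_time = T_end, lead = lead_side,
    trail = trail_side,
    t_penultimate = floor_t[m_floor - 1L], t_final = floor_t[m_floor],
    t_lead_landing = t_lead_land, t_trail_landing = t_trail_land,
    t_cross_lead = t_cross_lead, t_cross_trail = t_cross_trail,
    contact_times = list(left = vapply(plan$left, `[[`, numeric(1), "t_land"),
                         right = vapply(plan$right, `[[`, numeric(1),
                                        "t_land")),
    n_stances = list(left = length(plan$left) + 1L,
                     right = length(plan$right) + 1L),
    lead_pre = p$lead_pre, trail_pre = p$trail_pre,
    lead_post = p$lead_post, trail_post = p$trail_post,
    lead_stride = p$lead_stride, trail_stride = p$trail_stride,
    lead_clearance_mm = p$lead_clearance,
    trail_clearance_mm = p$trail_clearance,
    lead_velocity = p$lead_velocity, trail_velocity = p$trail_velocity,
    head_flexion = p$head, bve_m = p$bve,
    gaze_count_target = p$gaze_count, gaze_time_target = p$gaze_time,
    gaze_count_realised = gaze$count_realised,
    gaze_time_realised = gaze$time_realised,
    step = step)
  list(bundle = bundle, truth = truth)
}

#' Simulate a gaze stream with controlled AOI fixation structure
#'
#' Frames are budgeted so realised per-AOI fixation-time fractions match the
#' targets to within frame granularity; fixation counts follow the count
#' targets up to one-fixation granularity at ~2 fixations/s.  Separator runs
#' shorter than the 4-frame dwell threshold fill the non-fixation residual.
#'
#' @param trial_time trial duration (s).
#' @param count_targets,time_targets named percent targets over AOIs
#'   (`NA` = AOI absent).
#' @param present_aois AOIs present in the scene.
#' @param rate sampling rate (Hz).
#' @param fix_per_s nominal fixation rate used to size the fixation count.
#' @return list: `stream` (a [gaze_stream()]), `count_realised`,
#'   `time_realised` (named percent vectors).
#' @export
simulate_gaze_stream <- function(trial_time, count_targets, time_targets,
                                 present_aois, rate = 30, fix_per_s = 2) {
  N <- max(20L, round(trial_time * rate))
  K0 <- max(3L, round(fix_per_s * trial_time))
  aois <- present_aois
  Fa <- round(time_targets[aois] / 100 * N)
  na <- pmax(ifelse(count_targets[aois] > 0.5, 1L, 0L),
             round(count_targets[aois] / 100 * K0))
  na[Fa >= 4L] <- pmax(na[Fa >= 4L], 1L)   # time budget implies >=1 fixation
  # sub-threshold time budgets: force one minimal fixation or drop the AOI,
  # whichever leaves the realised time fraction closer to its target
  sub <- which(na > 0 & Fa < 4L)
  for (a in sub) {
    tgt <- time_targets[aois][a]
    if (is.na(tgt)) tgt <- 0
    if (abs(400 / N - tgt) <= tgt) Fa[a] <- 4L
    else { Fa[a] <- 0L; na[a] <- 0L }
  }
  na <- pmin(na, pmax(1L, floor(Fa / 4)))
  na[Fa == 0] <- 0L
  # keep the total inside the frame budget (reserve room for separator runs)
  reserve <- max(2L, 2L * max(na) - sum(na) - 1L)
  over <- sum(Fa) + reserve - N
  while (over > 0L) {
    slack <- Fa - 4L * na
    if (any(slack > 0L)) {
      a <- which.max(slack)
      take <- min(over, slack[a])
      Fa[a] <- Fa[a] - take
    } else if (any(na > 1L)) {
      a <- which.max(na)                  # drop a fixation from the busiest AOI
      na[a] <- na[a] - 1L
      Fa[a] <- Fa[a] - 4L
      take <- 4L
    } else break
    over <- sum(Fa) + reserve - N
  }
  # split each AOI's frame budget into >=4-frame runs
  runs <- list()
  for (a in aois) {
    if (na[[a]] == 0L) next
    base <- Fa[[a]] %/% na[[a]]
    lens <- rep(base, na[[a]])
    extra <- Fa[[a]] - sum(lens)
    if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
    # jitter lengths while preserving the sum and the 4-frame floor
    if (length(lens) > 1L) {
      for (it in seq_len(length(lens))) {
        i <- sample(length(lens), 2L)
        shift <- sample(0:max(0L, lens[i[1L]] - 4L), 1L)
        lens[i[1L]] <- lens[i[1L]] - shift
        lens[i[2L]] <- lens[i[2L]] + shift
      }
    }
    runs[[a]] <- lens
  }
  fix <- data.frame(aoi = rep(names(runs), vapply(runs, length, integer(1))),
                    len = unlist(runs, use.names = FALSE))
  if (!nrow(fix))
    return(list(stream = gaze_stream(rep("other", N), rate),
                count_realised = stats::setNames(rep(0, length(aois)), aois),
                time_realised = stats::setNames(rep(0, length(aois)), aois)))
  # order fixations to minimise same-AOI adjacency: repeated greedy picks of
  # the most frequent remaining AOI different from the previous one
  remaining <- table(fix$aoi)
  order_aoi <- character(nrow(fix))
  prev <- ""
  for (i in seq_len(nrow(fix))) {
    cand <- names(remaining)[remaining > 0]
    pick_from <- setdiff(cand, prev)
    if (!length(pick_from)) pick_from <- cand
    pick <- pick_from[which.max(remaining[pick_from])]
    order_aoi[i] <- pick
    remaining[pick] <- remaining[pick] - 1L
    prev <- pick
  }
  # match lengths to the ordered AOIs (shuffle within AOI)
  lens_by <- lapply(split(fix$len, fix$aoi),
                    function(v) if (length(v) == 1L) v else sample(v))
  taken <- stats::setNames(rep(0L, length(lens_by)), names(lens_by))
  ordered_len <- integer(nrow(fix))
  for (i in seq_len(nrow(fix))) {
    a <- order_aoi[i]
    taken[a] <- taken[a] + 1L
    ordered_len[i] <- lens_by[[a]][taken[a]]
  }
  # assemble with separator runs (always < 4 frames, label != both neighbours)
  G <- N - sum(ordered_len)
  k <- length(ordered_len)
  gap_budget <- integer(k + 1L)           # gaps before each fixation + tail
  forced <- c(FALSE, order_aoi[-1L] == order_aoi[-k], FALSE)
  gap_budget[forced] <- 1L
  spare <- G - sum(gap_budget)
  slot <- 2L
  while (spare > 0L) {                     # spread leftover into interior gaps
    if (gap_budget[slot] < 3L) {
      gap_budget[slot] <- gap_budget[slot] + 1L
      spare <- spare - 1L
    }
    slot <- slot + 1L
    if (slot > k + 1L) {
      if (all(gap_budget[2:(k + 1L)] >= 3L)) break
      slot <- 2L
    }
  }
  labels <- character(0)
  gap_label <- function(before, after, width) {
    pool <- setdiff(c(aois, "other"), c(before, after))
    if (!length(pool)) pool <- "untracked"
    rep(pool[1L], width)
  }
  for (i in seq_len(k)) {
    if (gap_budget[i] > 0L)
      labels <- c(labels, gap_label(if (i > 1L) order_aoi[i - 1L] else "",
                                    order_aoi[i], gap_budget[i]))
    labels <- c(labels, rep(order_aoi[i], ordered_len[i]))
  }
  if (gap_budget[k + 1L] > 0L)
    labels <- c(labels, gap_label(order_aoi[k], "", gap_budget[k + 1L]))
  if (spare > 0L) {                        # overflow: alternate sub-threshold runs
    fill <- setdiff(c(aois, "other"), labels[length(labels)])[1:2]
    fill <- fill[!is.na(fill)]
    while (spare > 0L) {
      w <- min(3L, spare)
      labels <- c(labels, rep(fill[1L], w))
      fill <- rev(fill)
      spare <- spare - w
    }
  }
  labels <- labels[seq_len(min(length(labels), N))]
  if (length(labels) < N) labels <- c(labels, gap_label(labels[length(labels)],
                                                        "", N - length(labels)))
  stream <- gaze_stream(labels, rate)
  fx <- detect_fixations(stream)
  all_aoi <- stats::setNames(rep(0, length(aois)), aois)
  cnt <- all_aoi; tim <- all_aoi
  if (nrow(fx)) {
    tb <- table(factor(fx$aoi, levels = aois))
    cnt[aois] <- as.numeric(tb) / nrow(fx) * 100
    dur <- vapply(aois, function(a) sum(fx$duration[fx$aoi == a]), numeric(1))
    tim[aois] <- dur / (N / rate) * 100
  }
  list(stream = stream, count_realised = cnt, time_realised = tim)
}

#' Degrade a gaze stream's tracking ratio
#'
#' Replaces randomly chosen samples with `untracked` so that the realised
#' tracked fraction equals `target_ratio` to within one sample.  A target at
#' or above the current ratio leaves the stream unchanged.
#'
#' @param stream a [gaze_stream()].
#' @param target_ratio desired tracked fraction in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a [gaze_stream()].
#' @export
degrade_tracking <- function(stream, target_ratio, seed = NULL) {
  stopifnot(target_ratio >= 0, target_ratio <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  labs <- stream$labels
  n <- length(labs)
  want_untracked <- round(n * (1 - target_ratio))
  have <- sum(labs == "untracked")
  if (want_untracked <= have) return(stream)
  tracked_idx <- which(labs != "untracked")
  flip <- sample(tracked_idx, want_untracked - have)
  labs[flip] <- "untracked"
  gaze_stream(labs, stream$rate)
}

#' Simulate a cohort of trials
#'
#' Per-participant random offsets (a `between_sd_frac` share of each
#' variable's published SD, shared across that participant's conditions) are
#' applied to the presets; the remaining variance is drawn per trial.
#' Deterministic under `seed`.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @param level `"parameters"` draws only the per-trial parameter values
#'   (fast; used for study-level statistics at scale); `"trajectories"`
#'   additionally synthesises full marker and gaze streams per trial.
#' @param ... passed to [simulate_trial()] when `level = "trajectories"`.
#' @return For `"parameters"`: data.frame of per-trial ground-truth values
#'   with participant/condition/repetition columns.  For `"trajectories"`:
#'   list of `simulate_trial()` results plus the same data.frame as
#'   attribute `"params"`.
#' @export
simulate_cohort <- function(design, seed = 1L,
                            level = c("parameters", "trajectories"), ...) {
  level <- match.arg(level)
  set.seed(as.integer(seed %% 2147483647))
  presets <- lapply(design$conditions, condition_presets)
  names(presets) <- design$conditions
  varnames <- setdiff(names(.preset_table), character(0))
  # participant offsets: one draw per variable, scaled by the mean SD of the
  # variable across the simulated conditions
  sd_avg <- vapply(varnames, function(v) {
    s <- vapply(design$conditions,
                function(cn) unname(presets[[cn]][[v]]["sd"]), numeric(1))
    mean(s, na.rm = TRUE)
  }, numeric(1))
  rows <- list(); trials <- list()
  within_scale <- sqrt(max(0, 1 - design$between_sd_frac^2))
  for (ip in seq_len(design$n_participants)) {
    pid <- sprintf("P%02d", ip)
    offs <- lapply(varnames, function(v) {
      if (is.na(sd_avg[[v]])) 0 else
        stats::rnorm(1L, 0, design$between_sd_frac * sd_avg[[v]])
    })
    names(offs) <- varnames
    for (cond in design$conditions) {
      for (rep_i in seq_len(design$repetitions)) {
        if (level == "parameters") {
          p <- draw_trial_params(presets[[cond]], sd_scale = within_scale,
                                 offsets = offs)
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pid, condition = cond, repetition = rep_i,
            trial_time = p$trial_time,
            lead_stride = p$lead_stride, trail_stride = p$trail_stride,
            lead_clearance_mm = p$lead_clearance,
            trail_clearance_mm = p$trail_clearance,
            lead_velocity = p$lead_velocity,
            trail_velocity = p$trail_velocity,
            lead_post = p$lead_post, trail_post = p$trail_post,
            bve_m = p$bve)
        } else {
          tr_seed <- (as.numeric(seed) * 7919 + length(trials) * 104729) %%
            2147483647
          tr <- simulate_trial(presets[[cond]], seed = tr_seed,
                               sd_scale = within_scale, offsets = offs,
                               participant_id = pid, repetition = rep_i, ...)
          trials[[length(trials) + 1L]] <- tr
          th <- tr$truth
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pid, condition = cond, repetition = rep_i,
            trial_time = th$trial_time,
            lead_stride = th$lead_stride, trail_stride = th$trail_stride,
            lead_clearance_mm = th$lead_clearance_mm,
            trail_clearance_mm = th$trail_clearance_mm,
            lead_velocity = th$lead_velocity,
            trail_velocity = th$trail_velocity,
            lead_post = th$lead_post, trail_post = th$trail_post,
            bve_m = th$bve_m)
        }
      }
    }
  }
  params <- do.call(rbind, rows)
  if (level == "parameters") params
  else structure(trials, params = params)
}
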
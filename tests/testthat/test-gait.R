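# Gait event detection and per-trial kinematics.

test_that("crossing instant: linear case, on-frame case, error case", {
  rate <- 100
  x <- seq(0, 2, length.out = 201)            # 0..2 m over 2 s
  toe <- marker_trajectory("toe", cbind(x, 0, 0.1), rate)
  expect_equal(crossing_instant(toe, 1.0), 1.0, tolerance = 1e-9)
  expect_equal(crossing_instant(toe, x[51]), 0.50)   # exactly on a frame
  expect_error(crossing_instant(toe, 5), "does not cross")
})

test_that("toe clearance converts to mm and flags virtual contact", {
  step <- step_geometry(edge_x = 1)
  toe <- marker_trajectory("toe", cbind(seq(0, 2, length.out = 201), 0, 0.217),
                           100)
  cl <- toe_clearance(toe, 1.0, step)
  expect_equal(as.numeric(cl), 142, tolerance = 1e-9)  # 0.217 - 0.075 m
  expect_false(attr(cl, "virtual_contact"))

  toe0 <- marker_trajectory("toe", cbind(seq(0, 2, length.out = 201), 0, 0.075),
                            100)
  expect_equal(as.numeric(toe_clearance(toe0, 1.0, step)), 0)
  toe_neg <- marker_trajectory("toe", cbind(seq(0, 2, length.out = 201), 0,
                                            0.05), 100)
  expect_true(attr(toe_clearance(toe_neg, 1.0, step), "virtual_contact"))
})

test_that("horizontal toe velocity: constant advance, stationary, boundary", {
  rate <- 100
  x <- 3.84 * (0:200) / rate
  toe <- marker_trajectory("toe", cbind(x, 0, 0.1), rate)
  expect_equal(horizontal_toe_velocity(toe, 1.0), 3.84, tolerance = 1e-9)
  still <- marker_trajectory("toe", cbind(1, 0, 0.1)[rep(1, 201), ], rate)
  expect_equal(horizontal_toe_velocity(still, 1.0), 0)
  expect_error(horizontal_toe_velocity(toe, 0.005), "boundary")
})

test_that("stationary foot yields a single stance spanning the trial", {
  step <- step_geometry(edge_x = 4)
  toe <- marker_trajectory("toe", cbind(1.3, 0.1, 0)[rep(1, 300), ], 100)
  heel <- marker_trajectory("heel", cbind(1.08, 0.1, 0)[rep(1, 300), ], 100)
  ct <- detect_foot_contacts(toe, heel, step)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$start_time, 0)
  expect_equal(ct$end_time, 2.99)
  expect_equal(ct$toe_x, 1.3)
  expect_equal(ct$surface, "floor")
})

test_that("lead/trail assignment follows the first-over-the-edge rule", {
  step <- step_geometry(edge_x = 4)
  mkc <- function(times, xs) data.frame(start_time = times, end_time = times + 0.3,
                                        contact_time = times, toe_x = xs,
                                        heel_x = xs - 0.22, y = 0, z = 0,
                                        surface = ifelse(xs > 4, "step", "floor"))
  right_first <- assign_lead_trail(mkc(c(1, 3.4), c(3.0, 4.8)),
                                   mkc(c(2, 2.8), c(3.6, 4.2)), step)
  expect_equal(right_first$lead, "right")    # right lands on step first
  expect_equal(right_first$trail, "left")
  left_first <- assign_lead_trail(mkc(c(2, 2.8), c(3.6, 4.2)),
                                  mkc(c(1, 3.4), c(3.0, 4.8)), step)
  expect_equal(left_first$lead, "left")
  expect_error(assign_lead_trail(mkc(1, 3.0), mkc(2, 3.6), step),
               "step not negotiated")
})

test_that("event ordering invariant holds on simulated trials", {
  for (s in 1:10) {
    r <- simulate_trial(condition_presets(conds[(s %% 4) + 1]), seed = 400 + s)
    gp <- extract_gait_parameters(r$bundle)
    ev <- gp$events
    expect_lt(ev$t_penultimate, ev$t_final)
    expect_lt(ev$t_final, gp$t_cross_lead)
    expect_lt(gp$t_cross_lead, ev$t_lead_landing)
    expect_lt(gp$t_cross_lead, gp$t_cross_trail)
    expect_lt(gp$t_cross_trail, ev$t_trail_landing)
    expect_equal(ev$lead, r$truth$lead)
  }
})

test_that("head flexion: calibration pose reads zero; known pitch recovers", {
  mk_head <- function(pitch_deg, n = 50L) {
    th <- pitch_deg * pi / 180
    off <- function(dx, dy, dz)
      marker_trajectory("h", cbind(dx * cos(th) + dz * sin(th), dy,
                                   1.6 - dx * sin(th) + dz * cos(th))[
                                     rep(1, n), ], 100)
    list(head_al_left = off(0.09, 0.075, 0.02),
         head_al_right = off(0.09, -0.075, 0.02),
         head_pl_left = off(-0.09, 0.075, 0.02),
         head_pl_right = off(-0.09, -0.075, 0.02))
  }
  cal <- mk_head(0)
  expect_equal(head_flexion(cal, cal, c(0.1, 0.2)), c(0, 0), tolerance = 1e-10)
  expect_equal(head_flexion(mk_head(32), cal, 0.25), 32, tolerance = 1e-8)
  expect_equal(head_flexion(mk_head(-10), 0, 0.25), -10, tolerance = 1e-8)
  expect_error(head_flexion(cal[1:3], NULL, 0.1), "head marker")
})

test_that("ml_bve: constant, alternating, brute-force oracle, invariances", {
  mk <- function(y) marker_trajectory("sternum", cbind(0, y, 1.35), 100)
  expect_equal(ml_bve(mk(rep(0.2, 50))), 0)
  alt <- rep(c(-1, 1), 25)
  expect_equal(ml_bve(mk(alt)), 1)
  expect_equal(ml_bve(mk(alt), mode = "as_printed"), 1)

  set.seed(12)
  y <- rnorm(200, sd = 0.3)
  direct <- sqrt(mean((y - mean(y))^2))
  expect_equal(ml_bve(mk(y)), direct, tolerance = 1e-12)
  expect_equal(ml_bve(mk(y), "as_printed"), direct^2, tolerance = 1e-12)
  # invariances: translation in y; linear scaling (RMS mode)
  expect_equal(ml_bve(mk(y + 3)), direct, tolerance = 1e-12)
  expect_equal(ml_bve(mk(2.5 * y)), 2.5 * direct, tolerance = 1e-12)
  expect_error(ml_bve(mk(0.5)), "at least 2")
})

test_that("extracted parameters are invariant to y-translation and time shift", {
  r <- simulate_trial(condition_presets("talk"), seed = 77, marker_noise_sd = 0)
  gp0 <- extract_gait_parameters(r$bundle)
  shifted <- r$bundle
  shifted$markers <- lapply(shifted$markers, function(m) {
    m$xyz[, 2] <- m$xyz[, 2] + 0.5
    m
  })
  gp1 <- extract_gait_parameters(shifted)
  for (f in c("lead_clearance_mm", "trail_clearance_mm", "lead_stride",
              "trail_stride", "lead_pre", "trail_pre", "lead_velocity",
              "bve_m"))
    expect_equal(gp1[[f]], gp0[[f]], tolerance = 1e-6)
})

test_that("flags: missing sternum, step never mounted", {
  r <- simulate_trial(condition_presets("read"), seed = 55)
  b <- r$bundle
  b$markers$sternum <- NULL
  gp <- extract_gait_parameters(b)
  expect_true(is.na(gp$bve_m))
  expect_true(any(grepl("sternum", gp$flags)))
  expect_false(is.na(gp$lead_clearance_mm))   # everything else populated

  # step far beyond the walkway: never negotiated
  b2 <- r$bundle
  b2$step <- step_geometry(edge_x = 40)
  gp2 <- extract_gait_parameters(b2)
  expect_true("negotiation_failure" %in% gp2$flags)
  expect_true(is.na(gp2$lead_stride))
})

test_that("foot positions and strides expose reporting conventions", {
  r <- simulate_trial(condition_presets("no_phone"), seed = 21,
                      marker_noise_sd = 0)
  gp <- extract_gait_parameters(r$bundle)
  ev <- gp$events
  pos <- foot_positions(ev, r$bundle$step$edge_x)
  pos_s <- foot_positions(ev, r$bundle$step$edge_x,
                          sign_convention = "signed")
  expect_equal(unname(pos_s["lead_pre"]), -unname(pos["lead_pre"]))
  expect_equal(unname(pos_s["lead_post"]), unname(pos["lead_post"]))
  st <- stride_lengths(ev)
  expect_equal(unname(st["lead"]), unname(pos["lead_pre"] + pos["lead_post"]),
               tolerance = 1e-9)
  heel <- foot_positions(ev, r$bundle$step$edge_x, ref_marker = "heel")
  # heel sits 0.22 m behind the toe, so it is farther short of the edge
  expect_equal(unname(heel["lead_pre"] - pos["lead_pre"]), 0.22,
               tolerance = 5e-3)
})
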
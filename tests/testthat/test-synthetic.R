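# Synthetic generator: presets, determinism, fidelity, cohort bookkeeping.

test_that("presets carry the published condition-level means and SDs", {
  w <- condition_presets("write")
  expect_equal(unname(w$trial_time), c(10.46, 3.23))
  expect_equal(unname(condition_presets("no_phone")$lead_clearance["mean"]),
               120)
  expect_equal(unname(condition_presets("read")$time_phone["mean"]), 60.97)
  expect_true(is.na(condition_presets("talk")$time_phone["mean"]))
  expect_false("phone" %in% condition_presets("no_phone")$present_aois)
  expect_error(condition_presets("email"), "unknown condition")
})

test_that("identical seeds give bit-identical bundles; different seeds differ", {
  a <- simulate_trial(condition_presets("read"), seed = 99)
  b <- simulate_trial(condition_presets("read"), seed = 99)
  expect_identical(a, b)
  c <- simulate_trial(condition_presets("read"), seed = 100)
  expect_false(identical(a$bundle$markers$toe_left$xyz,
                         c$bundle$markers$toe_left$xyz))
})

test_that("degenerate noise (sd 0, no marker noise) hits the preset means", {
  r <- simulate_trial(condition_presets("no_phone"), sd_scale = 0,
                      marker_noise_sd = 0, seed = 1)
  expect_equal(r$truth$lead_clearance_mm, 120)
  expect_equal(r$truth$trail_clearance_mm, 84)
  expect_equal(r$truth$lead_velocity, 3.84)
  expect_equal(r$truth$bve_m, 0.57)
  expect_equal(r$truth$head_flexion[["penultimate_contact"]], 1)
})

test_that("Monte-Carlo trial-time mean matches the write preset", {
  tt <- vapply(1:200, function(i)
    simulate_trial(condition_presets("write"), seed = i,
                   marker_noise_sd = 0)$truth$trial_time, numeric(1))
  expect_lt(abs(mean(tt) - 10.46), 0.5)
})

test_that("step edge is drawn inside the apparatus jitter window", {
  edges <- vapply(1:40, function(i)
    simulate_trial(condition_presets("talk"), seed = i)$truth$step$edge_x,
    numeric(1))
  expect_true(all(edges >= 3.95 & edges <= 4.05))
  expect_gt(diff(range(edges)), 0.02)
})

test_that("gaze stream realises its time fractions within 2 points", {
  for (cond in conds) {
    r <- simulate_trial(condition_presets(cond), seed = 600 + match(cond, conds))
    pres <- r$truth$gaze_count_target
    pres <- names(pres)[!is.na(pres)]
    dev <- abs(r$truth$gaze_time_realised[pres] -
                 r$truth$gaze_time_target[pres])
    expect_lt(max(dev), 2)
    # counts match up to fixation granularity, but only when every present
    # AOI's time budget can hold a 4-frame fixation (documented limitation:
    # a drawn AOI with ~0 time share but a positive count share is dropped)
    N <- length(r$bundle$gaze$labels)
    representable <- all(r$truth$gaze_time_target[pres] >= 400 / N)
    if (representable) {
      fx <- detect_fixations(r$bundle$gaze)
      gran <- 100 / nrow(fx)
      devc <- abs(r$truth$gaze_count_realised[pres] -
                    r$truth$gaze_count_target[pres])
      expect_lt(max(devc), 2 * gran + 2)
    }
  }
})

test_that("cohort sizes follow the design", {
  d252 <- simulate_cohort(cohort_design(21, repetitions = 3), seed = 1)
  expect_equal(nrow(d252), 252L)
  d68 <- simulate_cohort(cohort_design(17, repetitions = 1), seed = 1)
  expect_equal(nrow(d68), 68L)
  d8 <- simulate_cohort(cohort_design(2, repetitions = 1), seed = 1)
  expect_equal(nrow(d8), 8L)
  expect_identical(d252, simulate_cohort(cohort_design(21, repetitions = 3),
                                         seed = 1))
})

test_that("trajectory-level cohort carries bundles consistent with params", {
  tr <- simulate_cohort(cohort_design(2, conditions = c("no_phone", "write"),
                                      repetitions = 1), seed = 4,
                        level = "trajectories", marker_noise_sd = 0)
  expect_length(tr, 4L)
  pars <- attr(tr, "params")
  expect_equal(nrow(pars), 4L)
  expect_equal(tr[[1]]$truth$trial_time, pars$trial_time[1])
  expect_s3_class(tr[[1]]$bundle, "trial_bundle")
})

test_that("stance counts match the generator step plan", {
  for (s in 1:6) {
    r <- simulate_trial(condition_presets(conds[(s %% 4) + 1]), seed = 700 + s,
                        marker_noise_sd = 0)
    b <- r$bundle
    light <- filter_spec(cutoff = 15)
    for (side in c("left", "right")) {
      ct <- detect_foot_contacts(
        lowpass(b$markers[[paste0("toe_", side)]], light),
        lowpass(b$markers[[paste0("heel_", side)]], light), b$step)
      expect_equal(nrow(ct), r$truth$n_stances[[side]])
      # every ground-truth contact matched within 1 frame (10 ms)
      for (tc in r$truth$contact_times[[side]]) {
        expect_lt(min(abs(ct$contact_time - tc)), 0.010 + 1e-9)
      }
    }
  }
})

test_that("simulated cohorts reproduce the trial-time condition ordering", {
  ok <- 0L
  for (s in 1:25) {
    dat <- simulate_cohort(cohort_design(21, repetitions = 3), seed = 9000 + s)
    tab <- average_repetitions(data.frame(participant = dat$participant,
                                          condition = dat$condition,
                                          value = dat$trial_time))
    m <- colMeans(tab)
    if (m["write"] > m["read"] && m["read"] > m["talk"] &&
        m["talk"] > m["no_phone"]) ok <- ok + 1L
  }
  expect_gte(ok, 24L)
})
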
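# Fixation detection, AOI metrics, trial selection, inter-rater ICC.

test_that("tracking ratio counts tracked frames; threshold is inclusive", {
  s <- gaze_stream(c(rep("phone", 90), rep("untracked", 10)))
  expect_equal(tracking_ratio(s), 0.90)
  expect_false(select_analysis_trial(0.90)$excluded)    # >= 90% retained
  expect_equal(tracking_ratio(gaze_stream(rep("other", 5))), 1)
  expect_equal(tracking_ratio(gaze_stream(rep("untracked", 5))), 0)
  expect_error(tracking_ratio(gaze_stream(character(0))), "empty")
})

test_that("detect_fixations applies the 4-sample dwell rule", {
  s <- gaze_stream(c(rep("phone", 3), rep("travel_path", 5)))
  fx <- detect_fixations(s)
  expect_equal(nrow(fx), 1L)                 # 3-sample phone run rejected
  expect_equal(fx$aoi, "travel_path")
  expect_equal(fx$n_samples, 5L)
  expect_equal(fx$start_time, 3 / 30)
  expect_equal(nrow(detect_fixations(gaze_stream(character(0)))), 0L)
  # untracked runs never become fixations and break runs
  s2 <- gaze_stream(c(rep("phone", 4), rep("untracked", 6), rep("phone", 4)))
  expect_equal(nrow(detect_fixations(s2)), 2L)
  # duration-based rule: 120 ms = 3.6 frames at 30 Hz, so 4 frames qualify
  expect_equal(nrow(detect_fixations(s2, rule = "duration")), 2L)
  expect_equal(nrow(detect_fixations(gaze_stream(rep("phone", 3)),
                                     rule = "duration")), 0L)
})

test_that("detector equals the RLE oracle on random streams (min_samples 1-6)", {
  set.seed(42)
  for (i in 1:300) {
    s <- random_stream(sample(5:60, 1))
    for (ms in 1:6) {
      got <- detect_fixations(s, min_samples = ms)
      exp <- rle_fixation_oracle(s$labels, s$rate, ms)
      expect_identical(got$aoi, exp$aoi)
      expect_equal(got$start_time, exp$start_time)
      expect_equal(got$n_samples, exp$n_samples)
    }
  }
})

test_that("fixation durations respect trial duration and ordering", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_stream(sample(10:80, 1))
    fx <- detect_fixations(s)
    if (!nrow(fx)) next
    expect_lte(sum(fx$duration), length(s$labels) / s$rate + 1e-12)
    expect_true(all(diff(fx$start_time) > 0))
    # non-overlap
    expect_true(all(fx$start_time[-1] >=
                      (fx$start_time + fx$duration)[-nrow(fx)] - 1e-12))
  }
})

test_that("relative counts: forced arithmetic, absent AOIs, zero-fixation flag", {
  fx <- data.frame(aoi = c("phone", "phone", "other"),
                   start_time = c(0, 1, 2), duration = rep(0.2, 3),
                   n_samples = rep(6L, 3))
  rc <- aoi_relative_counts(fx)
  expect_equal(unname(rc["phone"]), 200 / 3, tolerance = 1e-10)
  expect_equal(unname(rc["other"]), 100 / 3, tolerance = 1e-10)
  expect_equal(unname(rc["travel_path"]), 0)

  pres <- c("travel_path", "surface_height_change", "other")
  rc2 <- aoi_relative_counts(fx[3, ], pres)
  expect_true(is.na(rc2["phone"]))          # absent AOI reported not-present
  expect_equal(unname(rc2["other"]), 100)
  expect_equal(unname(rc2["travel_path"]), 0)

  rc3 <- aoi_relative_counts(fx[0, ])
  expect_true(all(is.na(rc3)))
  expect_true(attr(rc3, "undefined"))

  # counts over present AOIs always sum to 100
  set.seed(5)
  for (i in 1:40) {
    s <- random_stream(60)
    fx <- detect_fixations(s)
    if (!nrow(fx)) next
    rc <- aoi_relative_counts(fx)
    expect_equal(sum(rc, na.rm = TRUE), 100, tolerance = 1e-8)
  }
})

test_that("relative time: full-trial fixation, none, and generator recovery", {
  fx <- data.frame(aoi = "phone", start_time = 0, duration = 2,
                   n_samples = 60L)
  rt <- aoi_relative_time(fx, trial_time = 2)
  expect_equal(unname(rt["phone"]), 100)
  rt0 <- aoi_relative_time(fx[0, ], trial_time = 2)
  expect_true(all(rt0[c("phone", "other")] == 0))

  # write-condition generator: recovered phone time within 2 points of target
  r <- simulate_trial(condition_presets("write"), seed = 31, sd_scale = 0)
  gm <- gaze_metrics(r$bundle$gaze, "write")
  expect_lt(abs(gm$rel_time["phone"] -
                  r$truth$gaze_time_target["phone"]), 2)
  expect_equal(unname(gm$rel_time["phone"]),
               unname(r$truth$gaze_time_realised["phone"]), tolerance = 1e-9)
})

test_that("first qualifying trial is selected; exclusions propagate", {
  s <- select_analysis_trial(c(0.85, 0.95, 0.99))
  expect_equal(s$selected, 2L)
  expect_true(select_analysis_trial(c(0.85, 0.80, 0.89))$excluded)
  expect_true(select_analysis_trial(c(0.99), calibration_ok = FALSE)$excluded)

  # cohort built so 17 of 21 participants qualify -> 68 observations
  trials <- expand.grid(participant = sprintf("P%02d", 1:21),
                        condition = conds, repetition = 1:3,
                        stringsAsFactors = FALSE)
  trials$tracking_ratio <- 0.97
  bad <- trials$participant %in% sprintf("P%02d", 1:4)
  trials$tracking_ratio[bad] <- 0.80
  sel <- select_cohort_trials(trials)
  expect_equal(sel$n_observations, 68L)
  expect_setequal(sel$excluded_participants, sprintf("P%02d", 1:4))
  expect_equal(nrow(sel$selected), 17L * 4L)
})

test_that("degraded tracking composes with the exclusion filter", {
  s <- gaze_stream(rep("travel_path", 100))
  expect_identical(degrade_tracking(s, 1.0, seed = 1), s)
  d <- degrade_tracking(s, 0.5, seed = 1)
  expect_equal(sum(d$labels == "untracked"), 50L)
  d89 <- degrade_tracking(s, 0.89, seed = 2)
  expect_lt(tracking_ratio(d89), 0.90)
  expect_true(select_analysis_trial(tracking_ratio(d89))$excluded)
})

test_that("inter-rater ICC: identity, shift invariance, ANOVA oracle", {
  a <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(interrater_icc(a, a)$icc, 1)
  expect_equal(interrater_icc(a, a + 0.7)$icc, 1)   # consistency definition

  # independent variance-components oracle via two-way aov
  set.seed(8)
  b <- a + rnorm(5, 0, 0.4)
  got <- interrater_icc(a, b)$icc
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(1:5, 2)), rater = factor(rep(1:2, each = 5)))
  ms <- anova(stats::lm(y ~ subj + rater, df))[["Mean Sq"]]
  exp_icc <- (ms[1] - ms[3]) / ms[1]
  expect_equal(got, exp_icc, tolerance = 1e-10)

  expect_true(interrater_icc(rep(1, 4), rep(1, 4))$undefined)
})
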
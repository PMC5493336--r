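# Repetition averaging, RM-ANOVA, pairwise comparisons, assumption checks,
# percent-change arithmetic.

test_that("average_repetitions: 84 cells, identity, plain mean, exclusion", {
  set.seed(2)
  df <- expand.grid(participant = sprintf("P%02d", 1:21), condition = conds,
                    repetition = 1:3, stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df))
  tab <- average_repetitions(df)
  expect_equal(dim(tab), c(21L, 4L))        # 84 cell means
  expect_equal(length(tab), 84L)

  one <- df[df$repetition == 1, ]
  t1 <- average_repetitions(one)
  expect_equal(t1["P01", "talk"],
               one$value[one$participant == "P01" & one$condition == "talk"])

  expect_equal(unname(average_repetitions(
    data.frame(participant = "a", condition = "talk",
               value = c(1, 2, 3)))[1, 1]), 2)

  # empty cell -> listwise exclusion, logged
  df2 <- df[!(df$participant == "P05" & df$condition == "read"), ]
  t2 <- average_repetitions(df2)
  expect_equal(nrow(t2), 20L)
  expect_identical(attr(t2, "excluded"), "P05")
})

test_that("rm_anova: degenerate cases and invariances", {
  tab <- matrix(rep(c(1, 2, 3, 4), each = 4), 4, 4,
                dimnames = list(NULL, conds))  # subjects differ, conditions equal
  an <- rm_anova(t(tab))
  expect_equal(an$F, 0)
  expect_equal(an$partial_eta_sq, 0)

  set.seed(31)
  tb <- matrix(rnorm(24), 6, 4)
  a1 <- rm_anova(tb)
  a2 <- rm_anova(tb + 100)                   # shift invariance
  expect_equal(a1$F, a2$F, tolerance = 1e-9)
  expect_equal(a1$p, a2$p, tolerance = 1e-9)
  expect_equal(a1$partial_eta_sq, a2$partial_eta_sq, tolerance = 1e-9)

  # zero error variance with a real condition effect: undefined flag
  und <- rm_anova(matrix(rep(c(1, 2), each = 3), 3, 2))
  expect_true(und$undefined)
})

test_that("rm_anova equals the SS-decomposition oracle on random tables", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(3:8, 1); k <- sample(2:5, 1)
    tb <- matrix(rnorm(n * k), n, k)
    got <- rm_anova(tb)
    exp <- rm_anova_oracle(tb)
    expect_equal(got$F, exp$F, tolerance = 1e-10)
    expect_equal(got$p, exp$p, tolerance = 1e-10)
    expect_equal(got$partial_eta_sq, exp$eta, tolerance = 1e-10)
  }
  # spot check against stats::aov as a fully independent path
  set.seed(8)
  tb <- matrix(rnorm(28), 7, 4)
  got <- rm_anova(tb)
  df <- data.frame(v = as.vector(tb), s = factor(rep(1:7, 4)),
                   c = factor(rep(1:4, each = 7)))
  av <- summary(stats::aov(v ~ c + Error(s), df))[[2]][[1]]
  expect_equal(got$F, av[["F value"]][1], tolerance = 1e-8)
  expect_equal(got$p, av[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("Bonferroni pairwise: identical data, multiply rule, oracle", {
  tb <- matrix(rep(c(5, 5, 5, 5), each = 6), 6, 4, dimnames = list(NULL, conds))
  pw0 <- bonferroni_pairwise(tb)
  expect_true(all(pw0$flagged))              # zero-variance differences

  set.seed(10)
  tb2 <- matrix(rnorm(24, mean = rep(c(0, 0.5, 1, 2), each = 6)), 6, 4,
                dimnames = list(NULL, conds))
  pw <- bonferroni_pairwise(tb2)
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 6))
  expect_true(all(pw$p_adj >= pw$p_raw))
  # oracle: manual paired t + multiply
  tt <- stats::t.test(tb2[, 1], tb2[, 3], paired = TRUE)
  row <- pw[pw$a == "no_phone" & pw$b == "read", ]
  expect_equal(row$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(row$p_adj, min(1, tt$p.value * 6), tolerance = 1e-10)
})

test_that("assumption checks behave on equal spreads and skewed data", {
  set.seed(3)
  base <- rnorm(12)
  tb <- cbind(base, base + 1, base - 2, base + 0.5)  # identical spreads
  colnames(tb) <- conds
  ch <- assumption_checks(tb)
  expect_gt(ch$levene$p, 0.95)
  expect_equal(nrow(ch$ks), 4L)

  # heavily skewed condition: KS rejects in most seeds
  rej <- 0L
  for (s in 1:40) {
    set.seed(s)
    x <- cbind(rnorm(25), exp(rnorm(25, sd = 1.5)))
    p <- assumption_checks(x)$ks$p[2]
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej, 25L)

  # cross-check Levene against an ANOVA on absolute deviations
  set.seed(4)
  tb2 <- matrix(rnorm(40, sd = rep(c(1, 3), each = 20)), 20, 2)
  got <- assumption_checks(tb2)$levene
  dev <- abs(sweep(tb2, 2, colMeans(tb2)))
  df <- data.frame(d = as.vector(dev), g = factor(rep(1:2, each = 20)))
  oracle <- anova(stats::lm(d ~ g, df))
  expect_equal(got$F, oracle$`F value`[1], tolerance = 1e-8)
  expect_equal(got$p, oracle$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("percent change: printed-value conventions and antisymmetry of sign", {
  expect_equal(percent_change(10.46, 6.27), 66.8, tolerance = 0.05)
  expect_equal(round_percent(percent_change(10.46, 6.27)), 67)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(round_percent(percent_change(0.80, 1.29)), -38)
  expect_error(percent_change(1, 0), "zero")
  set.seed(6)
  for (i in 1:25) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(sign(percent_change(a, b)), -sign(percent_change(b, a)))
  }
  expect_equal(round_percent(0.5), 1)
  expect_equal(round_percent(-0.5), -1)     # half away from zero
})

test_that("repetition effect check: identical durations and calibration", {
  expect_equal(repetition_effect_check(matrix(5, 10, 3))$F, 0)

  # type-I calibration under the null (no position effect)
  set.seed(14)
  rej <- 0L
  for (i in 1:400) {
    m <- matrix(rnorm(21 * 3, mean = 7, sd = 2), 21, 3)
    if (repetition_effect_check(m)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)

  # power against a strong monotone position effect (d = 1.5, n = 21)
  pow <- 0L
  for (i in 1:100) {
    m <- matrix(rnorm(21 * 3), 21, 3) + rep(c(0, 0.75, 1.5), each = 21)
    if (repetition_effect_check(m)$p < 0.05) pow <- pow + 1L
  }
  expect_gt(pow, 90L)
})

test_that("condition table: Monte-Carlo means, single participant, absent AOI", {
  dat <- simulate_cohort(cohort_design(21, repetitions = 3), seed = 17)
  df <- data.frame(participant = dat$participant, condition = dat$condition,
                   variable = "trial_time", value = dat$trial_time)
  agg <- stats::aggregate(value ~ participant + condition + variable,
                          data = df, FUN = mean)
  tab <- build_condition_table(agg)
  for (cn in conds) {
    tgt <- condition_presets(cn)$trial_time
    expect_lt(abs(tab[[paste0("mean_", cn)]] - tgt["mean"]),
              3 * tgt["sd"] / sqrt(21) + 0.3)
  }
  expect_lt(tab$p, 0.001)

  one <- agg[agg$participant == "P01", ]
  t1 <- build_condition_table(one)
  expect_true(is.na(t1$p))
  expect_equal(t1$sd_no_phone, 0)

  # phone AOI rows show "-" outside read/write in the formatted table
  gz <- data.frame(participant = rep(c("P01", "P02"), each = 4),
                   condition = rep(conds, 2), variable = "time_phone",
                   value = rep(c(NA, NA, 55, 80), 2))
  t2 <- build_condition_table(gz)
  out <- capture.output(format_condition_table(t2))
  expect_match(out[2], "\\-\t\\-")
})
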
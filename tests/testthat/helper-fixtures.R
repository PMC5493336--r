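# Shared fixture builders (everything generated in code at test time).

conds <- c("no_phone", "talk", "read", "write")

# small deterministic marker set for I/O tests
make_markers <- function(n = 10L, seed = 3L, rate = 100) {
  set.seed(seed)
  list(toe_left = marker_trajectory("toe_left", matrix(rnorm(3 * n), n), rate),
       sternum = marker_trajectory("sternum", matrix(rnorm(3 * n), n), rate))
}

# independent run-length-encoding oracle for fixation detection
rle_fixation_oracle <- function(labels, rate, min_samples) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "untracked" & r$lengths >= min_samples
  data.frame(aoi = r$values[keep],
             start_time = (starts[keep] - 1L) / rate,
             duration = r$lengths[keep] / rate,
             n_samples = r$lengths[keep])
}

random_stream <- function(n, rate = 30) {
  gaze_stream(sample(c("phone", "travel_path", "surface_height_change",
                       "other", "untracked"), n, replace = TRUE,
                     prob = c(0.3, 0.25, 0.1, 0.2, 0.15)), rate = rate)
}

# textbook sums-of-squares oracle for the one-way RM-ANOVA
rm_anova_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_err <- sum((tab - grand)^2) - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f,
       p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       eta = ss_cond / (ss_cond + ss_err))
}
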
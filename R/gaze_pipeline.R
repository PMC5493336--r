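# Visual-search metrics: dwell-threshold fixation detection, AOI metrics,
# tracking-ratio screening, trial selection and inter-rater reliability.

#' Tracking ratio of a gaze stream
#'
#' Fraction of frames with valid eye data (label not `untracked`).  Trials
#' with a ratio below 0.90 are conventionally excluded; the threshold is
#' inclusive (a ratio of exactly 0.90 is retained).
#'
#' @param stream a [gaze_stream()].
#' @return fraction in `[0, 1]`.
#' @export
tracking_ratio <- function(stream) {
  n <- length(stream$labels)
  if (n == 0L) stop("tracking_ratio: empty stream")
  sum(stream$labels != "untracked") / n
}

#' Detect fixations as dwell runs on one AOI
#'
#' A fixation is a maximal run of `min_samples` or more consecutive frames
#' with the same (non-`untracked`) AOI label.  Untracked frames and AOI
#' changes break runs; untracked gaps are never bridged.  At 30 Hz the
#' default 4-sample rule corresponds to a ~133 ms dwell; a duration-based
#' threshold (>= `min_duration` seconds) can be used instead via
#' `rule = "duration"`.
#'
#' @param stream a [gaze_stream()].
#' @param min_samples minimum run length in frames (default 4).
#' @param rule `"samples"` (default) filters runs by frame count;
#'   `"duration"` filters by `min_duration` seconds.
#' @param min_duration dwell threshold in seconds used when
#'   `rule = "duration"`.
#' @return data.frame with columns `aoi`, `start_time` (s), `duration` (s),
#'   `n_samples`, time-ordered and non-overlapping.
#' @export
detect_fixations <- function(stream, min_samples = 4L,
                             rule = c("samples", "duration"),
                             min_duration = 0.120) {
  rule <- match.arg(rule)
  stopifnot(min_samples >= 1L)
  labs <- stream$labels
  n <- length(labs)
  empty <- data.frame(aoi = character(0), start_time = numeric(0),
                      duration = numeric(0), n_samples = integer(0))
  if (n == 0L) return(empty)
  # explicit scan (the test oracle uses run-length encoding independently)
  aoi <- character(0); start <- integer(0); len <- integer(0)
  run_start <- 1L
  for (i in seq_len(n + 1L)) {
    boundary <- i > n || (i > 1L && labs[i] != labs[run_start])
    if (boundary) {
      run_len <- i - run_start
      lab <- labs[run_start]
      keep <- lab != "untracked" &&
        if (rule == "samples") run_len >= min_samples
        else run_len / stream$rate >= min_duration - 1e-12
      if (keep) {
        aoi <- c(aoi, lab); start <- c(start, run_start)
        len <- c(len, run_len)
      }
      run_start <- i
    }
  }
  if (!length(aoi)) return(empty)
  data.frame(aoi = aoi,
             start_time = (start - 1L) / stream$rate,
             duration = len / stream$rate,
             n_samples = len)
}

#' Relative number of fixations per AOI
#'
#' Each present AOI's fixation count as a percentage of the total fixation
#' count (the convention under which the published count columns sum to
#' ~100%).  An alternative per-unit-trial-time rate is available via
#' `per_time`/`trial_time`.
#'
#' @param fixations data.frame from [detect_fixations()].
#' @param present_aois AOIs present in the scene (the phone AOI is absent in
#'   the no-phone and talk conditions); absent AOIs are reported as `NA`.
#' @param per_time if `TRUE`, return fixations per AOI as a percentage of
#'   trial time (count / trial_time * 100) instead of count fractions.
#' @param trial_time trial duration in seconds (required when
#'   `per_time = TRUE`).
#' @return named numeric vector over `phone`, `travel_path`,
#'   `surface_height_change`, `other`; `NA` for absent AOIs.  If there are
#'   zero fixations, all values are `NA` and the attribute
#'   `undefined = TRUE` is set instead of an error.
#' @export
aoi_relative_counts <- function(fixations,
                                present_aois = setdiff(AOI_LEVELS, "untracked"),
                                per_time = FALSE, trial_time = NULL) {
  aois <- setdiff(AOI_LEVELS, "untracked")
  out <- stats::setNames(rep(NA_real_, length(aois)), aois)
  if (nrow(fixations) == 0L) {
    attr(out, "undefined") <- TRUE
    return(out)
  }
  counts <- table(factor(fixations$aoi, levels = aois))
  if (per_time) {
    stopifnot(!is.null(trial_time), trial_time > 0)
    vals <- as.numeric(counts) / trial_time * 100
  } else {
    vals <- as.numeric(counts) / nrow(fixations) * 100
  }
  out[aois] <- vals
  out[setdiff(aois, present_aois)] <- NA_real_
  out
}

#' Relative fixation time per AOI
#'
#' Summed fixation duration per AOI as a percentage of trial time.
#' Non-fixation time (saccades, sub-threshold runs, untracked frames) is the
#' residual to 100%.
#'
#' @param fixations data.frame from [detect_fixations()].
#' @param trial_time trial duration in seconds; must be > 0.
#' @param present_aois AOIs present in the scene; absent AOIs are `NA`.
#' @return named numeric vector of percentages (0 for present AOIs with no
#'   fixation).
#' @export
aoi_relative_time <- function(fixations, trial_time,
                              present_aois = setdiff(AOI_LEVELS, "untracked")) {
  stopifnot(trial_time > 0)
  aois <- setdiff(AOI_LEVELS, "untracked")
  dur <- vapply(aois, function(a)
    sum(fixations$duration[fixations$aoi == a]), numeric(1))
  out <- dur / trial_time * 100
  names(out) <- aois
  out[setdiff(aois, present_aois)] <- NA_real_
  out
}

#' Full visual-search metrics for one trial
#'
#' @param stream a [gaze_stream()].
#' @param condition phone condition (determines which AOIs are present: the
#'   phone AOI exists only in the read and write conditions).
#' @param min_samples fixation dwell threshold in frames.
#' @return list of class `gaze_metrics`: `trial_time`, `tracking_ratio`,
#'   `fixations`, `rel_count` and `rel_time` (named vectors),
#'   `present_aois`.
#' @export
gaze_metrics <- function(stream, condition, min_samples = 4L) {
  present <- if (condition %in% c("read", "write"))
    c("phone", "travel_path", "surface_height_change", "other")
  else c("travel_path", "surface_height_change", "other")
  fx <- detect_fixations(stream, min_samples = min_samples)
  trial_time <- length(stream$labels) / stream$rate
  structure(list(trial_time = trial_time,
                 tracking_ratio = tracking_ratio(stream),
                 fixations = fx,
                 rel_count = aoi_relative_counts(fx, present),
                 rel_time = aoi_relative_time(fx, trial_time, present),
                 present_aois = present),
            class = "gaze_metrics")
}

#' Select the analysis trial for one participant-condition cell
#'
#' The first trial (by occurrence) with tracking ratio >= 0.90 and good
#' pre/post calibration is retained; if none qualifies the cell is excluded.
#'
#' @param tracking_ratios numeric vector of per-trial tracking ratios in
#'   occurrence order.
#' @param calibration_ok logical vector of calibration flags (default all
#'   good).
#' @param threshold inclusive tracking-ratio threshold.
#' @return list with `selected` (1-based trial index, or `NA` if excluded)
#'   and `excluded` (logical).
#' @export
select_analysis_trial <- function(tracking_ratios,
                                  calibration_ok = rep(TRUE,
                                                       length(tracking_ratios)),
                                  threshold = 0.90) {
  stopifnot(length(tracking_ratios) >= 1L,
            length(calibration_ok) == length(tracking_ratios))
  ok <- tracking_ratios >= threshold & calibration_ok
  idx <- which(ok)
  if (!length(idx)) list(selected = NA_integer_, excluded = TRUE)
  else list(selected = idx[1L], excluded = FALSE)
}

#' Apply the trial-selection rule across a cohort
#'
#' Participants are excluded listwise: a participant contributes only if a
#' qualifying trial exists in every condition (the published bookkeeping:
#' 17 of 21 participants x 4 conditions x 1 occurrence = 68 observations).
#'
#' @param trials data.frame with columns `participant`, `condition`,
#'   `repetition`, `tracking_ratio` and optionally `calibration_ok`.
#' @param threshold inclusive tracking-ratio threshold.
#' @return list with `selected` (data.frame of retained trials, one row per
#'   participant-condition), `excluded_participants` (character vector) and
#'   `n_observations`.
#' @export
select_cohort_trials <- function(trials, threshold = 0.90) {
  stopifnot(all(c("participant", "condition", "repetition",
                  "tracking_ratio") %in% names(trials)))
  if (is.null(trials$calibration_ok)) trials$calibration_ok <- TRUE
  sel <- list(); excl <- character(0)
  for (p in unique(trials$participant)) {
    rows_p <- trials[trials$participant == p, , drop = FALSE]
    picks <- list(); ok_all <- TRUE
    for (cond in unique(rows_p$condition)) {
      cell <- rows_p[rows_p$condition == cond, , drop = FALSE]
      cell <- cell[order(cell$repetition), , drop = FALSE]
      s <- select_analysis_trial(cell$tracking_ratio, cell$calibration_ok,
                                 threshold)
      if (s$excluded) { ok_all <- FALSE; break }
      picks[[cond]] <- cell[s$selected, , drop = FALSE]
    }
    if (ok_all) sel[[p]] <- do.call(rbind, picks) else excl <- c(excl, p)
  }
  selected <- if (length(sel)) do.call(rbind, sel) else
    trials[0, , drop = FALSE]
  rownames(selected) <- NULL
  list(selected = selected, excluded_participants = excl,
       n_observations = nrow(selected))
}

#' Inter-rater intraclass correlation (two-way, average measures,
#' consistency)
#'
#' ICC(C,k) of McGraw & Wong for two coders' paired measurements:
#' `(MS_subjects - MS_error) / MS_subjects` from the two-way
#' subjects-by-raters ANOVA without interaction.  Consistency-type, so it is
#' invariant to an additive offset between coders.
#'
#' @param durations_a,durations_b paired measurements from the two coders;
#'   length >= 3.
#' @return list with `icc` (estimate in `[-1, 1]`, or `NA` with
#'   `undefined = TRUE` when both coders have zero variance) and the mean
#'   squares.
#' @export
interrater_icc <- function(durations_a, durations_b) {
  n <- length(durations_a)
  stopifnot(n == length(durations_b), n >= 3L)
  x <- cbind(durations_a, durations_b)
  k <- 2L
  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1L)
  ms_err <- ss_err / ((n - 1L) * (k - 1L))
  if (ms_rows < 1e-300 && ms_err < 1e-300)
    return(list(icc = NA_real_, undefined = TRUE,
                ms_subjects = ms_rows, ms_error = ms_err))
  list(icc = (ms_rows - ms_err) / ms_rows, undefined = FALSE,
       ms_subjects = ms_rows, ms_error = ms_err)
}
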
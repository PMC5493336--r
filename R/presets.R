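# Condition-level target means and SDs for the four phone conditions.

.preset_table <- local({
  conds <- c("no_phone", "talk", "read", "write")
  m <- function(...) stats::setNames(list(...), conds)
  list(
    trial_time       = m(c(4.79, 0.64), c(5.71, 0.57), c(6.27, 1.37),
                         c(10.46, 3.23)),
    lead_clearance   = m(c(120, 22), c(123, 23), c(127, 30), c(142, 28)),
    lead_velocity    = m(c(3.84, 0.51), c(3.15, 0.53), c(3.40, 0.46),
                         c(2.32, 0.59)),
    trail_clearance  = m(c(84, 21), c(87, 23), c(97, 28), c(90, 28)),
    trail_velocity   = m(c(3.09, 0.67), c(2.61, 0.44), c(2.61, 0.39),
                         c(1.91, 0.41)),
    bve              = m(c(0.57, 0.50), c(0.72, 0.73), c(0.61, 0.44),
                         c(1.35, 0.73)),
    lead_stride      = m(c(1.29, 0.14), c(1.11, 0.13), c(1.08, 0.17),
                         c(0.80, 0.18)),
    trail_stride     = m(c(1.26, 0.15), c(1.07, 0.17), c(1.09, 0.17),
                         c(0.70, 0.25)),
    lead_post        = m(c(0.22, 0.07), c(0.14, 0.08), c(0.21, 0.07),
                         c(0.13, 0.08)),
    trail_post       = m(c(0.94, 0.11), c(0.75, 0.17), c(0.84, 0.16),
                         c(0.49, 0.23)),
    head_penultimate = m(c(1, 9), c(2, 12), c(22, 15), c(32, 11)),
    head_final       = m(c(-1, 11), c(0, 15), c(17, 19), c(34, 13)),
    head_crossing    = m(c(2, 11), c(1, 14), c(20, 15), c(32, 11)),
    head_lead_after  = m(c(0, 11), c(1, 14), c(18, 17), c(32, 11)),
    head_trail_after = m(c(-10, 9), c(-7, 12), c(7, 16), c(31, 12)),
    count_phone      = m(c(NA, NA), c(NA, NA), c(37.83, 23.27),
                         c(55.34, 24.75)),
    count_shc        = m(c(17.07, 14.52), c(10.24, 7.42), c(6.73, 6.58),
                         c(6.77, 11.06)),
    count_path       = m(c(51.16, 19.20), c(37.35, 13.86), c(28.37, 17.33),
                         c(25.00, 18.60)),
    count_other      = m(c(29.74, 25.50), c(49.22, 21.56), c(23.05, 22.20),
                         c(9.62, 13.81)),
    time_phone       = m(c(NA, NA), c(NA, NA), c(60.97, 21.57),
                         c(88.18, 13.47)),
    time_shc         = m(c(16.95, 13.71), c(9.74, 9.46), c(3.55, 5.36),
                         c(1.51, 2.22)),
    time_path        = m(c(57.02, 20.29), c(46.49, 15.24), c(18.02, 14.94),
                         c(6.30, 9.52)),
    time_other       = m(c(16.25, 20.86), c(28.38, 18.94), c(8.14, 11.02),
                         c(0.01, 0.01))
  )
})

#' Condition-level target means and SDs
#'
#' Group means and standard deviations of every trial-level variable for one
#' of the four phone conditions, as published for the 21-participant cohort.
#' These are the generator's stated world: clearances in mm, velocities in
#' m/s, strides and foot placements in m, head flexion in degrees,
#' medial-lateral BVE in m, gaze count/time fractions in percent.  The phone
#' AOI is absent (`NA`) in the no-phone and talk conditions.
#'
#' @param condition one of `no_phone`, `talk`, `read`, `write`.
#' @return object of class `condition_preset`: a named list of `c(mean, sd)`
#'   pairs plus `condition` and `present_aois`.
#' @export
#' @examples
#' condition_presets("write")$trial_time   # 10.46 s mean, 3.23 s SD
condition_presets <- function(condition) {
  if (!condition %in% PHONE_CONDITIONS)
    stop(sprintf("condition_presets: unknown condition '%s'", condition))
  vals <- lapply(.preset_table, function(v) {
    out <- v[[condition]]
    names(out) <- c("mean", "sd")
    out
  })
  bad_sd <- vapply(vals, function(v) !is.na(v["sd"]) && v["sd"] < 0, logical(1))
  if (any(bad_sd)) stop("condition_presets: negative SD in preset table")
  vals$condition <- condition
  vals$present_aois <- if (condition %in% c("read", "write"))
    c("phone", "travel_path", "surface_height_change", "other")
  else c("travel_path", "surface_height_change", "other")
  structure(vals, class = "condition_preset")
}

#' Cohort design for synthetic studies
#'
#' @param n_participants number of participants (>= 2).
#' @param conditions phone conditions to simulate.
#' @param repetitions repetitions per participant-condition (>= 1).
#' @param between_sd_frac fraction of each variable's published SD assigned
#'   to stable between-participant variation; the remainder is
#'   within-participant trial-to-trial noise.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(n_participants = 21L,
                          conditions = PHONE_CONDITIONS,
                          repetitions = 3L,
                          between_sd_frac = 0.5) {
  stopifnot(n_participants >= 2L, repetitions >= 1L,
            all(conditions %in% PHONE_CONDITIONS),
            between_sd_frac >= 0, between_sd_frac <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 conditions = conditions,
                 repetitions = as.integer(repetitions),
                 between_sd_frac = between_sd_frac),
            class = "cohort_design")
}
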
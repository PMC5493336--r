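# phonegait

Measurement and analysis of **adaptive gait and visual search while using a
mobile phone**, in the step-negotiation paradigm: participants walk a 5.6 m
path and step up onto a low box (0.61 x 0.075 x 0.61 m, front rising edge at
3.95-4.05 m) while not using a phone, talking, reading, or writing a text.
A mobile eye tracker labels each 30 Hz gaze sample with an area of interest
(AOI: phone, intended travel path, surface height change, other), and a
motion-capture system records body markers at 100 Hz.

The package is aimed at movement scientists who need the complete pipeline
from raw per-trial streams to the study-level statistics:

* **Gaze**: fixations as runs of >= 4 consecutive identical AOI labels
  (~133 ms at 30 Hz); per-AOI relative fixation counts and times; tracking
  ratio with the inclusive 90 % screen; first-qualifying-trial selection;
  two-way average-measures consistency ICC for inter-rater reliability.
* **Gait**: foot contacts from marker speed/height thresholds with
  impact-centred refinement; lead/trail limb assignment (lead = first foot
  beyond the edge); sub-frame edge-crossing instant; vertical toe clearance
  (mm) and horizontal toe velocity (m/s) at the crossing; pre/post-edge foot
  placement and stride lengths; head flexion at five gait events;
  medial-lateral bivariate variable error (BVE) of the sternum,
  `sqrt(mean((y_i - mean(y))^2))`.
* **Statistics**: repetition averaging to one value per participant and
  condition; one-way repeated-measures ANOVA
  (`F = MS_condition / MS_error`, partial eta squared
  `SS_c / (SS_c + SS_e)`); Bonferroni-corrected paired comparisons; Levene
  and Kolmogorov-Smirnov assumption checks; percent-change reporting
  `100 (a - b) / b` rounded half-away-from-zero.
* **Synthetic trials**: `simulate_trial()` / `simulate_cohort()` generate
  marker and gaze streams from the published condition-level means/SDs with
  exact recorded ground truth, so the whole pipeline is testable at desk
  scale. See the methods vignette (`vignettes/phonegait-methods.Rmd`) for
  the model and its limits.

I/O: canonical marker CSV (`time, <marker>_x, _y, _z` in m/s), gaze CSV
(`time, aoi`), C3D motion-capture files (Intel format, configurable axis
map), and a flat-YAML metadata subset.

## Worked example

```r
library(phonegait)

# one synthetic write-condition trial with known ground truth
r  <- simulate_trial(condition_presets("write"), seed = 42)
gp <- extract_gait_parameters(r$bundle)
gp
#> <gait_parameters>
#>   clearance (mm): lead 110.8, trail 104.9
#>   crossing velocity (m/s): lead 2.64, trail 1.63
#>   stride (m): lead 0.972, trail 0.712
#>   BVE (m): 1.461 | flags: none
r$truth$lead_clearance_mm
#> [1] 111.0712

# gaze metrics for the same trial
gm <- gaze_metrics(r$bundle$gaze, "write")
round(gm$rel_time, 1)
#>                 phone           travel_path surface_height_change
#>                  74.9                  20.1                   0.9
#>                 other
#>                   0.0

# study-level statistics on a simulated 21-participant cohort
dat <- simulate_cohort(cohort_design(21, repetitions = 3), seed = 1)
tab <- average_repetitions(data.frame(participant = dat$participant,
                                      condition   = dat$condition,
                                      value       = dat$trial_time))
rm_anova(tab[, c("no_phone", "talk", "read", "write")])
#> RM-ANOVA: F(3, 60) = 138.247, p = 6.59e-27, partial eta^2 = 0.874
round_percent(percent_change(10.46, 4.79))   # write vs no-phone trial time
#> [1] 118
```

The lead foot cleared the edge by ~111 mm (the pipeline recovers the
generator's ground truth within 2 mm), ~75 % of this trial was spent
fixating the phone, and across a simulated cohort the phone condition has a
large, significant effect on trial time (partial eta squared ~0.87), with
writing more than doubling the no-phone trial time (+118 %).

## Command line

```sh
Rscript inst/cli/phonegait.R simulate --design design.yaml --out trials/ --seed 1
Rscript inst/cli/phonegait.R gaze  --trials trials/ --out metrics.csv
Rscript inst/cli/phonegait.R gait  --trials trials/ --out gait.csv --filter-cutoff 6
Rscript inst/cli/phonegait.R stats --gait gait.csv --gaze metrics.csv --out report/
```

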
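---
title: "Methods: measuring adaptive gait and visual search under phone dual-tasking"
author: "phonegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring adaptive gait and visual search under phone dual-tasking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Pedestrians who text, read or talk on a phone change both where they look
and how they walk. A standard laboratory paradigm walks participants along a
5.6 m path toward a low step-up box (0.61 m wide, 0.075 m high, 0.61 m deep)
whose front rising edge is placed 3.95-4.05 m from the start, while a
head-mounted eye tracker records gaze at 30 Hz and an optoelectronic system
records markers at 100 Hz. Four conditions are compared within participants:
`no_phone`, `talk`, `read` and `write`.

`phonegait` implements the full desk-scale analysis for this paradigm:

* **gaze**: dwell-threshold fixation detection on AOI-labelled sample
  streams, relative fixation counts and times per AOI, tracking-ratio
  screening, first-qualifying-trial selection, inter-rater ICC;
* **gait**: foot-contact events, lead/trail limb assignment, sub-frame edge
  crossing, vertical toe clearance, horizontal crossing velocity, foot
  placement and stride lengths, head flexion at five events, medial-lateral
  bivariate variable error (BVE) of the sternum;
* **statistics**: repetition averaging, one-way repeated-measures ANOVA with
  partial eta squared, Bonferroni pairwise comparisons, Levene and
  Kolmogorov-Smirnov checks, and the percent-change arithmetic used in
  condition comparisons;
* **synthetic data**: a trial generator with exact, recorded ground truth so
  that every stage of the pipeline can be verified without access to raw
  laboratory recordings.

Conventions: x is anterior (toward the step), y medial-lateral, z up; time
in seconds from trial start; 0-based frames; half-open intervals.

## Gaze metrics

A fixation is a maximal run of at least 4 consecutive identical AOI labels
(`phone`, `travel_path`, `surface_height_change`, `other`); `untracked`
frames and AOI changes break runs, and untracked gaps are never bridged.
The published description attaches "(120 ms)" to the 4-frame rule, which is
inconsistent at 30 Hz (4 frames = 133 ms); the frame rule is the operational
statement and is the default, with a duration-threshold mode
(`rule = "duration"`, >= 120 ms) available. Neither is asserted to be the
original authors' intent.

The *relative number of fixations* is implemented as each AOI's share of the
total fixation count, because the published count columns sum to ~100%;
the literal "per unit trial time" reading is available via `per_time = TRUE`.
*Relative fixation time* is summed fixation duration over trial time; the
residual to 100% is non-fixation time. The tracking-ratio exclusion
threshold is inclusive at 0.90. Inter-rater reliability uses the two-way
average-measures consistency ICC, i.e. `(MS_subjects - MS_error) /
MS_subjects`, which is invariant to a constant offset between coders.

## Gait kinematics

Markers: bilateral distal second toe, second metatarsal head, calcaneus and
lateral malleolus; sternum; four head markers (antero-/postero-lateral).
Missing samples are linearly interpolated for gaps of at most 10 frames
(100 ms); longer gaps invalidate the dependent variables of that marker.

**Two filter bands.** The field's conventional smoothing for 100 Hz
kinematics is a zero-phase 4th-order Butterworth at 6 Hz, and that is the
default for planted positions, strides and sternum sway. However, the
zero-phase 6 Hz kernel rings over roughly +/-0.15 s. The crossing of the
step edge is a fast transient - in the write condition the toe decelerates
from ~2.3 m/s to rest within ~0.15 m - and the heavy band measurably biases
the clearance (several mm) and the crossing velocity (up to ~0.3 m/s), and
delays threshold-based stance onsets. Instantaneous quantities (crossing
instant, toe clearance, crossing velocity, head pitch) and event detection
therefore use a lighter 15 Hz band (`filter_spec(crossing_cutoff = )`).
This is a deliberate deviation from a single-band design: the single band
cannot meet the package's own recovery tolerances on trials with
published-magnitude kinematics.

**Events.** Stance = toe speed < 0.2 m/s and toe height within 15 mm of the
supporting surface (floor, or box top between the edges) for >= 100 ms.
The contact instant is refined at the upward crossing of vertical velocity
through -0.2 m/s (half a typical 0.4 m/s foot-fall descent): a symmetric
zero-phase filter leaves that crossing centred on the true contact. The
lead foot is the first to contact ground beyond the edge; penultimate and
final floor contacts are the last two stances short of the edge. The
crossing instant interpolates linearly between the last frame before and the
first frame past the edge within the swing.

**Placement reference.** Pre- and post-edge foot positions default to the
toe marker. A heel default for post-edge placement was considered and
rejected: with the published condition means, heel-referenced placement
implies a negative trail-foot pre-edge distance (the trail foot would plant
beyond the edge before stepping up), i.e. an infeasible geometry. The
`ref_marker = "heel"` option remains for sensitivity analyses. Pre/post
distances are reported as positive magnitudes by default; the published
signed convention (negative = before the edge) is available.

**BVE.** The medial-lateral bivariate variable error is the dispersion of
the sternum's y-coordinate about its trial mean. The published formula can
be read with or without a square root; the default is the root mean squared
deviation (metres), and `mode = "as_printed"` returns the mean squared
deviation. The two coincide for unit deviations. Either way, published
magnitudes (0.57-1.35 m) are very large for sternum sway; the generator
treats them as the stated world without asserting physiological plausibility.

## Statistics

The one-way repeated-measures ANOVA is computed from the within-subject
sums-of-squares decomposition, with uncorrected degrees of freedom by
default (a Greenhouse-Geisser correction is available by flag, but the
original analysis reports none). Partial eta squared is
`SS_condition / (SS_condition + SS_error)`. Pairwise comparisons are paired
t-tests with p-values multiplied by the number of pairs and capped at 1;
paired-samples Cohen's d is reported alongside. Levene's test uses
mean-centred absolute deviations; normality is checked per condition with a
one-sample Kolmogorov-Smirnov test against a normal with the sample moments.
Percent changes are `100 * (a - b) / b`, rounded to the nearest integer with
halves away from zero - the convention that reproduces every checkable
printed percentage.

## The synthetic generator

`simulate_trial()` draws one trial's targets from condition presets (the
published condition-level means and SDs for every variable) and constructs:

* a footfall schedule: uniformly spaced approach plants ending at the lead
  and trail final floor plants, then the two crossing steps; the trial
  duration equals the drawn trial time, absorbed by the approach cadence;
* swing trajectories: minimum-jerk horizontal profiles, except crossing
  swings, which use Hermite profiles with a constant-velocity window of
  ~60 ms around the edge so that the drawn crossing velocity and clearance
  are attained *exactly* at the crossing and survive band-limited
  measurement; the vertical arc rises through the clearance point on its
  smooth rising limb, stays above the box across its span for the trail
  foot, and ends with a constant-velocity (0.4 m/s) touchdown pad;
* head pitch: piecewise-smooth through the five event targets with short
  plateaus at each event and a 150 deg/s rate limit (people do not rotate
  their heads faster mid-gait; the limit also decouples the realised pitch
  from event-timing jitter). Rate-limited values are recorded as ground
  truth;
* sternum sway: a sum of low-frequency sinusoids scaled so the realised
  RMS deviation equals the drawn BVE exactly;
* gaze: a run-structured stream whose per-AOI fixation frames are budgeted
  to match the drawn *time* fractions within 2 points; separator runs
  shorter than 4 frames fill the residual.

**Feasibility repairs.** Independent Gaussian draws from the published
means/SDs can be jointly infeasible. The generator repairs such draws
minimally and records realised values as ground truth: crossing swings are
required to last >= 0.35 s with >= 0.14 s on either side of the edge and a
descent no faster than gravity allows (placements move outward/backward as
needed); a trial time too short for the drawn swing durations is extended at
a brisk cadence; head-pitch excursions are rate limited.

**What is emulated and what is not.** The generator reproduces the
condition-level distributions, the within-participant/between-participant
variance split (by default 50% of each published SD is a stable participant
offset - the publication does not decompose variance, so recovery tests
target generator ground truth, not published SDs), the apparatus jitter of
the step position, tracking-ratio degradation, and exact per-trial ground
truth. It does not emulate: the initial 0.13 m obstacle (out of analysis
scope), muscle/joint dynamics, genuinely curved walking paths (sway is
noise about a straight line), scene-video content behind the AOI labels, or
correlated draws between variables (each variable is drawn independently
about its participant offset). A green recovery test therefore establishes
that the pipeline measures what the generator encodes at stated tolerances -
not that the generator is a biomechanical model of walking.

**Known representational limits.** At ~2 fixations/s, a single fixation is
5-15% of a trial's fixation count, so the published *count* fractions
cannot generally be realised within 2 points (the write condition's
"Other" row - 9.6% of counts but 0.01% of time - is internally
inconsistent with a 4-frame minimum dwell at any realistic trial length).
The generator prioritises time fractions (always within 2 points) and
realises counts up to fixation granularity; drawn AOIs whose time share
cannot hold even one 4-frame fixation are dropped or given one minimal
fixation, whichever leaves the realised time closer to its target.

## Numerical choices

* Butterworth coefficients by bilinear transform; forward-backward filtering
  with odd-reflection padding; derivative by central differences.
* Sub-frame evaluation of crossing time, clearance and velocity by linear
  interpolation; contact refinement as described above.
* C3D support covers the Intel processor type with float or scaled-integer
  point data; positions are converted to metres via `POINT:UNITS` (float32
  storage limits cross-format agreement to ~1e-7 m).
* Zero error variance in the ANOVA yields F = 0 for condition-invariant
  data and an `undefined` flag otherwise; zero-variance pairwise difference
  vectors are flagged rather than tested.
* Seeds: all generator randomness flows through R's RNG from a single
  integer seed; cohort simulation derives per-trial seeds below 2^31.

## Limitations

* The generator's swing shapes are convenient smooth profiles, not fitted to
  real swing kinematics; only the constrained quantities (clearance,
  velocity, placements, timing) are calibrated.
* Gaze streams have controlled run structure but no saccade dynamics or
  scanpath realism.
* The statistics layer implements the study's design (one within factor,
  four levels); it is not a general ANOVA package.
* Head flexion assumes the four head markers are rigidly attached and the
  calibration pose is available or zero-referenced.
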
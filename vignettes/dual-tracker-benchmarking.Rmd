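---
title: "Benchmarking dual eye-tracker recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking dual eye-tracker recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazebench implements the analysis pipeline used to compare a high-rate
laboratory eye tracker with a low-rate webcam-based one when both record the
same viewer simultaneously: a five-task stimulus battery, synchronization of
the two asynchronous gaze streams, real-time dispersion-based fixation
detection, the standard data-quality metrics, and a factorial-ANOVA summary
stage. Because raw dual recordings of this kind are rarely shareable, the
package also ships a parametric simulator of the whole measurement chain, so
every stage is testable end to end and parameter-recovery claims can be
checked against known ground truth.

```{r setup}
library(gazebench)
```

## Geometry

All metrics are expressed in degrees of visual angle on a flat screen viewed
from a fixed distance (defaults: 381 mm diagonal, 1440 x 900 px, 600 mm —
`default_screen()`). Conversion is per-axis about the screen centre:

\[
\theta_x = \arctan\!\left(\frac{(x - w_{px}/2)\, p_x}{D}\right)\frac{180}{\pi},
\qquad p_x = \frac{w_{mm}}{w_{px}},
\]

and analogously for y, with the pixel sign convention (y grows downward)
inherited so nothing silently flips. We use per-axis `atan` rather than the
exact angle between 3-D gaze vectors: on this geometry the two differ by
less than 0.1 degree anywhere on screen, and per-axis angles keep x and y
separable for the per-axis precision metrics. Angular distance is the
Euclidean norm of the per-axis difference; it agrees with the small-angle
linear form within 1% for displacements up to 200 px here.

## The simulator

The simulator separates the *viewer* from the *instruments*.

`gen_ground_truth_gaze()` produces a compliant viewer on a fine regular
timeline (500 Hz by default): gaze sits on fixation targets plus an
i.i.d. Gaussian tremor (default SD 0.05 deg — a stand-in for physiological
fixational instability, not a spectral model of it), moves between targets
in constant-duration 40 ms linear ramps (the battery never analyzes saccade
dynamics, so velocity profiles would add nothing testable), follows pursuit
targets with a gain (0.95) and a latency (100 ms), and blinks as a Poisson
process (0.1 Hz, 100–300 ms). Confirmation key presses land 250 ± 50 ms
after target offset with log-normal durations (median 250 ms, log-SD 0.35),
so a few percent of presses exceed the 500 ms bound and exercise the
rejection rule of the offset-fixation selection.

`observe_tracker()` then views that truth through a `tracker_model()`:
nominal rate with Gaussian timestamp jitter, processing latency, a constant
clock offset, a systematic bias plus per-sample Gaussian noise applied in
degree space, random dropouts and loss episodes. Loss is reported in either
of the two conventions found in practice — a retained row with confidence 0
(webcam-style) or a missing row (lab-style) — because the data-loss metric
must handle both. The shipped presets (`lab`: 500 Hz, bias 0.5 deg, noise
0.3 deg/axis; `webcam`: 30 Hz, bias 1.0 deg, noise 0.7 deg/axis) bracket
the magnitudes typical of the two device classes; they are presets for
simulation, not measurements of any particular device.

The pursuit stimulus is the battery's Brownian-direction target: the
direction angle diffuses with variance 887 deg²/s (the battery's standard
setting), position advances at constant speed, and the target reflects
specularly off the screen edges. The speed law is not prescribed by the
battery, so each trial draws a constant speed uniformly from a configurable
range (default 100–400 px/s) — the simplest faithful option. Samples whose
step involved a reflection are flagged so that diffusion estimates
(`pursuit_direction_variance()`) can exclude the deterministic angle
changes.

Free viewing has no instructed target; simulated viewers visit 3–6 random
fixation clusters per image. Only between-tracker correlations are computed
downstream, so image content is irrelevant to the pipeline and no saliency
model is attempted.

What the simulator does *not* emulate: smooth head-movement-dependent loss
(head-task loss rates come from the same dropout/blink model as everywhere
else), pupil dynamics, microsaccades, saccadic velocity profiles, or
calibration drift over time. Passing tests therefore demonstrate that the
pipeline recovers known parameters from data with realistic sampling
structure and loss — not that any particular real tracker meets these
numbers.

Between-subject variability enters through the scenario: each simulated
subject draws a personal calibration bias around the preset one
(`subject_bias_sd_deg`, defaults 0.7 deg webcam / 0.5 deg lab). This is
what gives the across-subject precision analysis something real to measure;
with identical subjects those SDs collapse to the centroid noise floor.

## Synchronization

The two streams share no clock. `estimate_lag()` snaps both onto a uniform
auxiliary grid (averaging samples that land in one cell) and scans integer
grid shifts for the one maximizing the mean of the x- and y-axis Pearson
correlations over jointly observed cells, ties broken toward the smaller
absolute lag. The grid step defaults to the *resampling-target* (low-rate)
stream's nominal rate, e.g. 33.3 ms at 30 Hz, and that step is the
precision to which the lag is resolved. A finer grid is available via
`grid_hz`, but resolving the lag much below the low-rate sampling interval
is not statistically meaningful: around the optimum the correlation
objective is flat to well within its own sampling noise, while at the
low-rate step the objective's curvature dominates the noise and recovery to
one step is reliable (the acceptance suite verifies 20/20 recoveries over
offsets spanning ±1 s at noise SD up to 1 deg).

`align_and_resample()` linearly interpolates the high-rate stream at the
low-rate timestamps from the two bracketing *valid* samples, and marks the
result invalid when a bracket is missing or the bracketing span exceeds
`max_gap_ms` (default 100 ms — shorter than a typical blink, so blinks are
never bridged; bridged blinks would silently corrupt the data-loss metric).
There is no extrapolation beyond the stream ends. The merged series keeps
the low-rate stream's native timestamps as the common timebase, converts
both streams to degrees, and a merged row is valid only where both sources
are. A single constant lag is removed; clock-rate (linear drift) fitting is
deliberately out of scope.

## Fixation detection

The detector is a real-time, single-pass dispersion algorithm (I-DT
family): a candidate opens when `min_points` (≥ 3) consecutive valid
samples have dispersion at or below the threshold; each further sample is
added while the dispersion stays below threshold *and* its relative growth
`(new - old)/old` stays below `max_relative_change`; when only the
relative-growth test fails the detector may *slide* — add the new sample
and evict the oldest — provided that does not increase the dispersion; any
other failure, or an invalid sample, closes the fixation. Scanning resumes
at the first sample after the last member, so fixations never overlap.

Numerical conventions worth stating:

* **Dispersion functional.** Maximum pairwise Euclidean distance in degree
  space. Unlike the classic I-DT box measure (x-extent + y-extent, kept as
  `measure = "bounding_box"` for cross-checks), it is rotation-invariant.
  It is also monotone under window extension, which is what makes the
  detector's greedy extension equivalent to an exhaustive maximal-window
  search when the slide and relative-growth rules are disabled — the
  property the oracle-equivalence tests exploit.
* **Growth from zero.** If the current dispersion is exactly 0 (all points
  coincident), the relative-growth test passes by convention: relative
  growth from zero is undefined and rejecting it would make noiseless data
  pathologically fragment.
* **Evicted samples stay members.** The slide step removes the oldest
  sample from the *window* but the closed fixation still spans it. This
  conserves samples — every valid sample belongs to at most one fixation —
  at the cost that, in slide-heavy stretches, a member's distance to the
  final centroid may slightly exceed the threshold.
* **Defaults.** Threshold 1.0 deg, `min_points` 3, relative growth 0.5,
  minimum duration 100 ms. These are defaults, not battery constants; the
  battery scenario raises the threshold to 3 deg because its webcam preset
  has 0.7 deg/axis sample noise, and a threshold below the typical pairwise
  sample distance (≈ 2σ√2) cannot admit three consecutive samples at all.

The offset-related fixation of a grid trial is the fixation containing the
confirmation press, with press duration under 500 ms; both criteria are
evaluated per tracker, and ambiguity resolves toward the fixation with the
longest overlap with the trial.

## Quality metrics

* **Accuracy**: Euclidean angular distance between the selected fixation's
  centroid and the target.
* **Eccentricity**: a grid target is *outer* when it lies on the boundary
  ring (first/last row or column; 26 outer and 30 inner on the 7 x 8 grid),
  else *inner*. The exact class map is overridable, since reasonable
  designs differ here.
* **Across-subject precision**: per-axis sample SD (n−1) of selected
  centroids across subjects at each shared grid location, then the grand
  mean and SD of those SDs across locations per tracker. Locations with a
  single contributor are excluded and reported, not imputed.
* **RMS-S2S**: root-mean-square of successive sample-to-sample
  displacements per axis within fixation intervals, pairs spanning invalid
  samples excluded. For i.i.d. noise of SD σ it converges to σ√2.
* **Data loss**: percent of confidence-0 samples (confidence mode) or
  1 − observed/expected samples with expected = interval × nominal rate,
  rounded down (missing mode).
* **Axis correlations**: per-axis Pearson r on jointly valid merged rows;
  subjects under 30 such rows are flagged and excluded from cohort
  averages. The cohort value is the plain arithmetic mean of per-subject r
  (the conventional report); Fisher-z averaging is available behind a flag
  as the statistically cleaner variant.
* **Drift correction**: per-axis *median* (robust to one bad recalibration
  fixation; mean behind a flag) of centroid-minus-target offsets over a
  seven-point recalibration grid, subtracted from subsequent samples. The
  reported residual is leave-one-out cross-validated — each point's error
  under a correction fitted on the others — so it does not reward
  overfitting the recalibration points themselves.

## Statistics

`factorial_anova()` fits the full factorial linear model and reports
Type-II sums of squares: for each term, the residual-sum-of-squares drop
from adding it to the model containing every term that does not contain it
(marginality respected). Type-II is order-invariant and standard for
two-level designs with the mild imbalance that trial exclusions create;
it is computed by direct model comparison so that exactly-saturated designs
(zero residual) still decompose, and it is cross-checked against an
independent implementation in the test suite. Effect sizes are η² =
SS_effect / SS_total; p values are uncorrected, by design, and documented
as such. The battery runs accuracy ~ tracker x eccentricity x task-half on
trial-level records, and per-axis precision ~ tracker x eccentricity on
location-level SDs.

`paired_ttest()` is the classic two-sided paired t; a zero-variance
difference vector raises an error instead of returning infinities, because
in this pipeline it almost always signals a degenerate simulation (the
battery catches this and reports an NA row, so intentionally degenerate
scenarios still complete).

`kde_heatmap()` evaluates a Gaussian-kernel density on a raster and
normalizes by the maximum (peak exactly 1, the usual display scale).
Bandwidth defaults to Scott's rule per axis, σ·n^(−1/6).

## The battery run

`run_battery()` wires everything together per subject and task: simulate →
observe with both trackers → estimate and remove the clock lag (the
battery gives the lab tracker a 150 ms clock offset against the display
clock, mirroring the usual two-computer setup; the webcam shares the
display clock) → merge → detect → metrics → statistics, and emits a
battery-wide summary table (loss mean/SD, per-axis correlations, fixation
and offset-fixation counts, accuracy and precision mean/SD per tracker),
the three ANOVA tables, the loss t tests, and a run log containing the
seed and a config hash — no timestamps, so reruns are bit-identical.

Default problem sizes are chosen for quick, well-powered simulated runs:
six subjects, the full 56-target grid at 1.5 s per trial, two 15 s pursuit
trials, six 4 s images, and the two head tasks; the test suite uses
slightly smaller variants of the same scenario. These sizes are package
choices for simulation studies, not properties of any real experiment,
and all of them are plain scenario fields.

## Known limitations

* The lag model is a single constant offset; real clock *rate* mismatch
  over long sessions would need piecewise or linear-drift estimation.
* Correlation is blind to constant offsets and scalings between trackers;
  it complements, and never replaces, the accuracy and precision metrics.
* Across-subject precision confounds between-subject calibration bias with
  centroid noise; the simulator makes this explicit
  (SD ≈ √(β² + σ_centroid²), verified by a recovery test) but real data
  cannot separate the two without repeated targets within subjects.
* The detector is deliberately real-time and single-pass; offline
  detectors with lookahead (two-means clustering and similar) are out of
  scope.
* The simulator's viewer is compliant and stationary; attention lapses,
  head-pose-dependent accuracy and asymmetric loss are not modelled.
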
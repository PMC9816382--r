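---
title: "The Swing Performance Index: model, assumptions, and design choices"
author: "golfSPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Swing Performance Index: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golfSPI)
```

## The problem

A golf swing generates clubhead speed through coordinated transverse-plane
rotations of the pelvis and the upper torso. Professionals execute these
rotations with striking consistency; amateurs differ both in magnitude and in
timing. Conventional performance measures (handicap, driving distance,
clubhead speed at impact) say nothing about rotational technique. The Swing
Performance Index (SPI) condenses a small set of rotational-velocity metrics
into one score anchored to a professional reference cohort: professionals
average 100 with a standard deviation of 10, and larger deviations from the
average professional swing map to lower scores.

## From markers to metrics

Six markers drive everything: the bilateral anterior superior iliac spines
(ASIS) define the pelvis segment, the bilateral acromia define the upper
torso, one marker sits on the distal club shaft (5 cm from the clubface
centre), and one on the ball.

**Segment orientation.** Per frame, the left-minus-right marker vector is
projected onto the horizontal plane and its `atan2` angle taken in degrees,
then unwrapped so no between-frame jump exceeds 180 degrees. Frames where the
projected vector nearly vanishes (norm below 1 nm, or a missing sample)
inherit the previous frame's angle rather than produce a wild value.

**Rotational velocity.** The derivative is a central finite difference,
`(theta[t+1] - theta[t-1]) * rate / 2`, one-sided at the endpoints. Central
differences were chosen for their second-order accuracy and zero phase lag;
the source data dialect does not record which scheme the original capture
pipeline used, so this is an explicit package decision. X-prime is the
pelvis-minus-torso velocity at each instant; during the downswing the torso
outpaces the pelvis, making X-prime negative there.

**Handedness and axes.** The vertical axis is explicit metadata (default
`z+`) rather than inferred from the data, because the event rules depend on
vertical displacement and inference from noisy trajectories is fragile.
Positive rotation is toward the target for a right-handed golfer
(counter-clockwise seen from above); the `handedness` flag flips the sign so
downswing pelvis/torso velocities are positive either way.

**No default filtering.** Velocities are computed from raw unwrapped angles.
An optional zero-lag low-pass (fourth-order magnitude response, forward-
backward Butterworth; `cutoffHz` argument) is available for noisy captures.
For body-segment kinematics at 240 Hz a 12 Hz cutoff is a conventional
choice and is what the package's own noisy-recovery tests use. Be aware of
an intrinsic limit: instantaneous values of small magnitude - X-prime at
impact especially, around -170 deg/s - sit close to the noise floor left by
any reasonable smoothing of 1 mm marker noise (about +/-8 deg/s), so their
*relative* recovery error can exceed 5% even when the large velocity peaks
are recovered to within 2-3%.

## Swing events

Four events segment the swing, all defined on marker kinematics:

* **Backswing start**: first frame whose absolute vertical clubhead speed
  exceeds 0.2 m/s, sustained for at least `minHold = 5` frames (about 21 ms
  at 240 Hz). The threshold is the published rule; the sustain requirement
  is a package decision that rejects single-frame noise spikes, and the
  absolute value accommodates takeaways that dip before rising.
* **Top of backswing**: maximal vertical clubhead position between start and
  impact, ties resolved to the latest frame. This event bounds the downswing
  window; it is operationally defined here because only the boundary between
  backswing and downswing matters for the metrics.
* **Impact**: the frame immediately preceding the first increase in ball
  velocity. The launch threshold is 0.5 m/s - far above marker noise, far
  below any real launch speed - and ball speed uses a backward difference so
  the first *moving* frame crosses the threshold and impact lands exactly on
  the last static frame. The ball must be quasi-static (below 0.05 m/s)
  before the swing.
* **Follow-through end**: first local minimum of vertical clubhead
  displacement after impact (first frame of a minimal plateau); if the
  height decreases monotonically to the end of the recording the last frame
  is used, with a warning.

**Clubhead speed at impact (CSI).** The distal-shaft marker speed is the
one-frame displacement after impact times the sampling rate. Because the
marker sits 5 cm inboard of the clubface centre, a circle is fitted to the
marker trajectory over the 50 frames on each side of impact (total least
squares plane, then algebraic least squares circle in the plane) and the
marker speed is scaled by `(r + 0.05) / r`. Degenerate fits (collinear
trajectories, straight paths) fall back to the raw marker speed with a
warning; windows clipped by the recording extent use all available frames,
with a minimum of ten.

## The nine candidate metrics

For each of pelvis, torso, and X-prime rotational velocity: the signed peak
over the downswing (top of backswing to impact, inclusive), the value at the
impact frame, and the signed peak over the follow-through (impact exclusive
to follow-through end inclusive). Peaks are extrema of maximal *absolute*
magnitude with sign preserved, because follow-through X-prime peaks are
large negative values. The pre-impact window starts at the top of the
backswing, not at the backswing start, so backswing-direction extrema cannot
masquerade as downswing peaks.

## The index

For a chosen subset of one to three metrics, fitting proceeds in a fixed
order:

1. **Pro-referenced z-scoring.** Each metric is centred and scaled by the
   professional cohort's mean and *population* standard deviation - never
   the pooled distribution - so amateur deviations remain visible.
2. **SMOTE balancing.** The amateur group is oversampled in the normalized
   subset space until both groups are equal: repeatedly, a random original
   amateur row and its single nearest neighbour (Euclidean, among original
   amateur rows) are joined and a uniformly random point on the segment
   added. The single-neighbour variant follows the procedure's wording;
   the conventional five-neighbour variant is deliberately not used. The
   RNG seed is a required argument and is stored in the fitted model.
3. **Pro-fitted PCA.** Principal components come from the eigen-
   decomposition of the professional rows' population covariance; all
   components are kept, ordered by decreasing eigenvalue, with each
   component's sign fixed so its largest-magnitude loading is positive.
   The sign convention makes saved models reproducible across linear-algebra
   backends; distances, hence scores, are sign-invariant anyway.
4. **Log-distance scaling.** Every row (original and synthetic) is
   transformed to PCs; `d` is its Euclidean distance to the professional PC
   centroid, `l = log(max(d, epsilon))`, and

   `SPI = 100 - 10 * (l - mean_pro(l)) / popsd_pro(l)`.

   The slope is negative: swings farther from the average professional swing
   score lower. By construction the professional scores have mean exactly
   100 and population SD exactly 10.

Three numerical choices deserve comment. The *population* SD convention is
used in both scaling stages because it reproduces the published worked
example's integer scores, where the sample-SD variant drifts by about one
point on the extreme rows; it is documented as empirically selected. The
floor `epsilon = 1e-6` keeps the logarithm finite for a swing coinciding
with the professional centroid (such a swing receives the maximal finite
score). The logarithm base is configurable but irrelevant: z-scoring absorbs
the constant factor exactly, which the tests assert numerically.

## Subset selection

All subsets of up to three of the nine metrics - 9 + 36 + 84 = 129 - are
enumerated. Each subset of two or more variables is screened by the overall
Kaiser-Meyer-Olkin measure of sampling adequacy, computed from the
correlation matrix and its anti-image partial correlations; subsets below
0.6 are excluded. The threshold is *inclusive* and applies to the overall
measure only, since in the published selection an individual variable at
0.57 survived while the overall value of 0.62 passed. Two consequences are
worth knowing: a single variable has no defined KMO, so singletons bypass
the screen; and any two-variable set has overall KMO exactly one half (the
anti-image partial correlation of a pair equals its raw correlation), so
pairs can never pass a 0.6 screen - the effective competition is between
singletons and triples. By default the KMO uses the original (pre-SMOTE)
rows of both groups; `kmoPopulation` switches to balanced rows or
professionals only, since the source procedure does not state which rows
enter the computation.

Surviving subsets get an SPI model (fitted once on the full dataset, all
sharing one seed) and are ranked by the AUC of a leave-one-swing-out
cross-validated single-feature logistic regression on the scores, original
and synthetic rows included. Held-out probabilities are pooled and the AUC
is their Mann-Whitney statistic with ties counted one half. Folds with
complete separation still yield probabilities monotone in the score (which
is all the AUC consumes); a fold missing one class predicts the training
prior. Ties in the ranking prefer smaller subsets, then canonical order.
The cross-validation unit is one swing, matching how the reference data are
tabulated; `groupBy = "subject"` switches to leave-one-participant-out, and
`nested = TRUE` refits the entire SPI pipeline inside each fold for
sensitivity analysis. Both alternatives are provided because the source
procedure specifies neither.

## The synthetic-swing generator

No raw recordings are distributed with the reference study, so the package
ships a generator whose defaults *are* the professional study conditions:
designed velocity peaks at the published professional magnitudes (pelvis
415.2 / 288.8 / 309.8 deg/s and torso 551.7 / 458.5 / 929.2 deg/s for
downswing / impact / follow-through), 240 Hz sampling, clubhead speed 33.15
m/s, pelvis width 0.30 m, shoulder width 0.40 m, club arc radius 1.4 m
(the widths and radius are plausibility constants used only as ground
truth). Velocity profiles are piecewise raised-cosine pulses - smooth,
with closed-form extrema at designed phases - integrated on a four-times
supersampled grid; bilateral markers sit at half the segment width
perpendicular to each segment's orientation about fixed centres, making the
segments exactly rigid. The club marker rides a tilted circular arc whose
angular profile realises the designed takeaway crossing, top-of-backswing
height maximum, post-impact height minimum, and impact speed; the
impact-to-bottom piece is a cubic Hermite with zero angular acceleration at
impact so the one-frame marker displacement measures the designed speed to
better than 0.1%. The ball is static until the impact frame, then departs
at constant velocity well above the launch threshold.

The amateur preset is an invented, parameter-documented degradation -
velocity means scaled by 0.75, SDs doubled, pelvis peak delayed within the
downswing, clubhead speed centred at 30.58 m/s. No claim of amateur realism
is made; the preset exists to give the pipeline two separable groups with
known truth. Likewise the generator does not emulate soft-tissue artefact,
marker occlusion patterns, autocorrelated noise, or inter-trial variability
within a participant, so passing recovery tests demonstrate correctness of
the computation chain, not robustness to every artefact of real captures.

Ground truth is by construction: designed metric values are evaluated from
the analytic velocity profiles on the frame grid with the same window rules
the extractor uses, and the takeaway/top frames are defined operationally on
the noiseless club trajectory. Noise-free recovery of all nine metrics is
within 0.7% in practice (asserted at 2%); with 1 mm Gaussian marker noise
and a 12 Hz zero-lag low-pass, the designed pelvis peaks recover within 5%,
while small at-impact values are relative-error-limited as discussed above.

## Reference cohort fixture

The package embeds a 44-row reference cohort - 22 professional swings (11
participants, two swings each) and 22 amateur rows (5 originals plus 17
SMOTE oversamples) - as principal-component triples with their published
integer SPI scores. Refitting the scaling stage on the professional rows
reproduces 43 of the 44 printed integers exactly and the remaining row
within one point (a 95.51 that prints as 95); the amateur rows average 83
(SD 4), the strongest professional averages 122 across his two swings,
the pro/amateur standardized mean difference is 2.11, and leave-one-out
logistic classification of the scores attains an AUC of 0.973. These are
the quantities `scripts/acceptance.R` recomputes.

## Problem sizes and determinism

The test suite and acceptance script run on the bundled 44-row fixture and
on simulated cohorts of 11 professionals and 5 amateurs (one swing each,
two-second recordings at 240 Hz) - the reference study's cohort shape.
Every stochastic step (preset draws, marker noise, SMOTE) flows through a
single seeded generator per call and restores the caller's RNG state, so
identical seeds give bit-identical recordings, models, and rankings.

## Known limitations

* The SPI is only as good as its reference cohort; with 22 professional
  swings the PCA loadings and scaling constants are small-sample estimates,
  and a different cohort would shift both.
* The KMO pair degeneracy above means the screening step never admits
  two-metric subsets at the conventional threshold.
* TRC and the package's CSV dialect are the only recording formats; C3D is
  out of scope by design (convert externally).
* Events are defined on the club and ball markers only; recordings that cut
  off before the follow-through minimum fall back to the last frame.
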
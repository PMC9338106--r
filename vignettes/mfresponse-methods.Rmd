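---
title: "Methods: simulating and measuring manual following responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring manual following responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfresponse)
```

## The phenomenon and the task

When people reach out to tap a moving target, motion that appears near the
planned movement endpoint pulls the ongoing movement in the motion's
direction — the *manual following response*. The paradigm implemented here
probes that response with an interception task: a 2-cm target moves
rightward at 30 cm/s across a large screen and must be tapped inside a 6-cm
interception zone that the target's center crosses 667 ms after the target
appears. A square — either a filled *tile* that occludes the patterned
background, or an open *frame* that does not — is centered on the zone and,
300–400 ms after the target appears, translates left or right at 20 cm/s for
100 ms (2 cm of displacement). Both square types create the same local edge
motion; they differ only in whether the surface under the movement endpoint
itself appears to move. Square sides of 7, 37 and 67 cm place the nearest
moving edge 3.5, 18.5 and 33.5 cm from the endpoint.

The headline measurement is the **response curve**: the mean lateral finger
velocity on rightward-motion trials minus that on leftward-motion trials, as
a function of time over the first 300 ms after the square's motion onset,
computed per participant and condition. The **response magnitude** is the
mean of that curve between 150 and 200 ms after motion onset. Because the
original raw marker data are not deposited, this package pairs the analysis
with a synthetic trajectory generator whose injected response is known
exactly, so the whole pipeline can be validated by parameter recovery.

## The synthetic trajectory generator

Each trial produces a 3-D fingertip-marker trajectory sampled at exactly
500 Hz (2-ms intervals), in screen coordinates: x rightward, y upward (cm,
origin at screen center), z the perpendicular distance to the screen.

**Baseline reach.** The finger rests on a starting point 30 cm below the
interception zone and moves along a minimum-jerk path in the screen plane to
a planned contact point, starting 100 ms after the target appears. The
contact time is drawn per trial from a normal distribution with mean 662 ms
and SD 27 ms — the screen-contact latency the original sessions report. The
simulated participant *tracks* the target: the planned contact point is the
target's position at the drawn contact time, plus isotropic endpoint scatter
(SD 0.62 cm per axis). That scatter is the one calibrated quantity in the
generator: it is set so that about 70% of taps land inside the target, the
hit rate the original sessions report. Perpendicular to the screen the
finger lifts along `z(τ) = h·6.75·τ²(1−τ)` (peak lift `h` = 15 cm), a
smooth asymmetric profile chosen because it leaves the screen gently but
returns with a realistic, clearly supra-threshold approach speed
(`6.75·h/T` ≈ 180 cm/s) and stops abruptly at contact — which is exactly
the event the deceleration-based tap detector must find. A symmetric
profile that lands at zero velocity would make taps undetectable by the
paradigm's own rule, which presupposes rapid tapping.

**Injected response.** The following response is added to x as a velocity
perturbation

v(t) = gain(side, kind) · 20 cm/s · K((t − t_on − λ)/w) · sign(direction),

with K a raised-cosine bump of unit peak on [0, 1], latency λ = 120 ms and
width w = 150 ms, so the injected response rises from 120 to 270 ms after
motion onset — the latency range such responses show. Position is the
closed-form integral of this bump, so forward differencing recovers the
injected velocity exactly (up to noise), which is what makes sharp oracle
tests possible. Default gains are 0.10, 0.085 and 0.05 for the 7-, 37- and
67-cm squares, identical for frame and tile: a small drop from small to
medium and a clear drop to the large square, mirroring the finding that the
response weakens with the eccentricity of the edge-motion signal but
ignores the surface interpretation. These give window-mean magnitudes of
about 3.1, 2.7 and 1.6 cm/s — the few-cm/s scale such responses have. All
gains are configuration-overridable, so the pipeline can equally be tested
on data that violate the finding.

**Noise and artifacts.** Marker noise is additive Gaussian with SD 0.01 cm
per coordinate (optical motion capture grade). With probability 1% a trial
contains one contiguous dropped-sample gap of 10–50 samples; the gap is
placed inside the analysis window (motion onset to onset + 300 ms) so that
the generator's missing rate coincides with the 1% of trials the original
analysis removed for missing data — a gap elsewhere in the trial would not
trigger removal, and nothing in the study constrains where real dropouts
occurred. With probability 0.5% the square's motion is executed (and
recorded) 9–20 ms away from its commanded onset, beyond the one-display-frame
(8.3 ms) tolerance, emulating the <1% of trials removed for timing issues.
A rigid marker-to-screen miscalibration (rotation + offset) can be applied
so the four-point calibration stage is exercised end to end.

What the generator does **not** emulate: biomechanics (muscle dynamics,
joint constraints), between-participant variability in response gain or hit
rate (all simulated participants share one model, so across-participant
SDs are far tighter than the ±11% hit-rate spread across real
participants), target-tracking submovements, and any dependence of the
response on trial history. Passing recovery tests therefore shows the
*analysis* is unbiased and correctly sized for data of this structure — not
that real hands move like minimum-jerk reaches.

## Kinematic operators

**Calibration.** Four marker positions recorded while touching four known
screen locations determine a plane and, within it, an exact projective map
(homography) onto screen coordinates; the perpendicular distance is taken
along the fitted plane normal, oriented by a point known to lie on the
participant's side. An exact four-point homography is used rather than an
affine least-squares fit because four correspondences determine a plane
projectivity exactly — residuals at the calibration points are at machine
precision, and the synthetic rotation+offset miscalibration round-trips to
within 10⁻⁶ cm.

**Velocity.** Lateral position is differentiated directly — a forward
difference over every 2-ms interval, indexed to the interval start, with no
smoothing. Intervals touching a missing sample are flagged missing.

**Tap detection.** With the per-sample approach Δᵢ = zᵢ₋₁ − zᵢ, the tap is
the first sample where the approach drops by more than 1 mm between
consecutive measurements (Δᵢ₋₁ − Δᵢ > 0.1 cm) while the finger is within
2 cm of the screen. The 1-mm-per-sample-pair criterion is the normative
rule; expressed as a deceleration over one 2-ms sample pair it corresponds
to 250 m/s², and the threshold is a parameter (`threshold`, cm per sample
pair) so other conventions can be explored. The target counts as hit when
the fingertip lies within the target's outline at the tap time (boundary
inclusive), and likewise for the interception zone.

## The response analysis

Trials are removed when the recorded square-motion onset or offset deviates
from the commanded time by more than one 120-Hz display frame, or when any
sample is missing in the analysis window; all other trials are kept
irrespective of performance. Each trial's velocity series is re-indexed to
lag after *its own* recorded motion onset (nearest-sample alignment, ≤1 ms
of jitter that averages out across trials). Alignment is to the recorded
onset rather than a fixed offset from target appearance because the onset
varies over 300–400 ms by design; only onset-locking makes a 150–200-ms
response window meaningful. The curve lives on the 2-ms grid over 0–298 ms
(150 points); the magnitude window 150–200 ms is endpoint-inclusive — 26
grid points. Velocity samples at or after the detected tap are excluded
from averaging, since the finger has landed; late motion onsets (≈400 ms)
combined with early contacts (≈600 ms) otherwise leak post-landing zeros
into the window. Per-direction means are plain averages; unequal trial
counts after exclusion are not reweighted.

Group summaries are across-participant means with standard errors
(SD/√n). The tile-vs-frame magnitude pairing is summarized by a
standardized major-axis slope (sign(r)·SD(tile)/SD(frame)) with a
participant-level bootstrap interval: both axes carry comparable noise, so
ordinary least squares would be attenuated below 1 even when the true
relation is the identity.

## Numerical and design choices

* Sampling is exact: times are `(0:n)·0.002` s, never accumulated floats.
* The screen's physical backward tilt is ignored; everything lives in
  screen-plane coordinates, which is where the analysis operates.
* Motion-onset times are drawn continuously from 300–400 ms rather than
  quantized to 120-Hz display frames; the analysis aligns to the recorded
  onset either way, and continuous draws exercise every alignment phase.
* Degenerate inputs fail loudly: calibration with three collinear points, a
  condition with no trials in one direction, a magnitude window the curve
  does not cover, fewer than two participants for a SEM, unknown
  configuration keys.
* Per-trial seeds are drawn from the session seed, and per-participant
  seeds from the run seed, so every artifact is reproducible from one
  integer and sessions are bit-identical across runs.

## Problem sizes used in validation

The packaged checks run the pipeline at the study's size — 12 participants,
2 blocks of 25 trials per condition cell and direction (600 trials each) —
for parameter recovery (an ensemble of such experiments under the default
gains; recovered group-mean magnitudes are unbiased within 5%), the
frame-tile equivalence check (paired differences within 3 SE of zero), the
size-ordering check across independent seeds, and a zero-gain null
calibration (every condition within 3 SE of zero). Tap detection is
validated on noise-free sessions against the generator's ground-truth
contact sample and on hand-constructed descent series where the rule's
firing sample is derived by hand.

## Known limitations

* The baseline reach is stylized; no claim is made that its velocity
  profile matches real interception movements beyond endpoint timing, and
  recovery results validate the analysis, not the motor model.
* Homogeneous simulated participants make across-participant SEMs smaller
  than real ones; tests that compare means to SEs are therefore conservative
  about analysis bias but say nothing about real between-participant spread.
* The tap detector is run offline over the full trajectory; the original
  experiment detected taps on-line for feedback. The rule is identical, but
  causality constraints of a real-time implementation are out of scope.
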
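---
title: "Methods: automated saccade, blink and pupil analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated saccade, blink and pupil analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculopipe)
```

This vignette describes the models and procedures the package implements,
the assumptions behind them, the parameters that matter, and the design
decisions taken where the problem was genuinely open. The companion
synthetic-session generator is described last, together with what passing
its checks does and does not establish about real recordings.

## Signal model and pre-processing

Input is monocular gaze (`T, X, Y, A`: timestamp, horizontal and vertical
position in screen pixels, pupil area in camera pixel counts), nominally
at 500 Hz, segmented into trials of the interleaved pro/anti-saccade task
(IPAST): 1000 ms inter-trial interval, 1000 ms central fixation whose
colour instructs the trial, a 200 ms gap, and a stimulus 10° left or
right. All per-trial clocks are re-zeroed at stimulus onset.

*Timestamp repair.* Duplicated stamps are dropped (first kept); missing
stamps in gaps of at most 100 ms are restored by linear interpolation of
`X`, `Y`, `A` and flagged invalid. Longer gaps are genuine loss, not stamp
glitches: the grid is restored with the last gaze value held and `A = 0`,
so downstream loss detection sees them. Event stamps are rounded to the
sample step with half-step ties rounded down — an arbitrary but
deterministic convention.

*Units.* `deg = atan((px − centre) · cm_per_px / distance) · 180/π`
per axis, rightward/upward positive. The inverse is exact, which the
tests verify to below 1e−9 px.

*Smoothing.* One primitive is used everywhere: a width-`w` moving average
run forward and then backward (zero phase), with odd-reflection padding of
length `3(w−1)` so edges carry no transient. Constants and linear ramps
pass through unchanged. Simplicity is deliberate: asymmetric or
higher-order filters distort the starts and ends of velocity transients
and can amplify post-saccadic oscillations.

The default width is `w = 4` samples at 500 Hz (scaled proportionally at
other rates), and it was *calibrated*, not assumed: on synthetic saccades
with known kinematics, `w = 5` attenuates the peak velocity of 2–8°
saccades by 5–8% (their velocity peaks last only a few samples), while
`w = 3` leaves enough sample noise for the max-picking peak estimator to
inflate small-saccade peaks by a comparable amount. `w = 4` holds the
total peak-velocity measurement error near 2–3% across 2–15°.

*Velocity.* Three-point central differences
(`v_i = (x_{i+1} − x_{i−1}) / 2Δs`, two-point at the ends) on the smoothed
positions; speed is the Euclidean norm of the two smoothed component
velocities.

*Drift re-referencing.* Between drift-corrections the calibration may be
offset by a constant. Per drift segment, samples of the final 500 ms of
the fixation period with speed below 50 deg/s are pooled across trials and
the modal position on a 0.1° histogram (range ±5°, ties toward zero) is
subtracted. The mode — not the mean — is used because saccades away from
fixation skew means but barely move the mode. The 0.1° bin is well below
fixational jitter; the epoch choice ("the final 500 ms") matters little
because the mode is insensitive to occasional excursions. Offsets are
estimated per segment from pooled trials rather than per trial: per-trial
modes are noisier and a within-segment calibration is constant by
construction.

## Blink detection

Loss of pupil data is not always a blink (lashes, mascara, looking away),
and a blink is longer than its data loss: the lid occludes the pupil
progressively, so the area ramps down before the tracker gives up and
wavers after reacquisition. The chain is:

1. **Normalize**: `A₃₀₀ = A / mean(A[A>10]) × 300`. Areas at or below 10
   are loss or near-loss and are excluded from the mean; 300 is an
   arbitrary common scale. The informative mean of the result is exactly
   300 per trial (a test asserts this to 1e−6 relative).
2. **Flatten**: the slow (luminance/arousal) modulation is modelled by
   linearly interpolating across abnormal samples (|smoothed area
   velocity| > 1000 units/step at 500 Hz, or `A₃₀₀` outside 200–400) and
   smoothing the repaired copy with a 50-point zero-phase boxcar; the
   model is subtracted and 300 added back, so the fixed loss thresholds
   below apply regardless of drift. The velocity sign is treated as
   irrelevant (the printed threshold is one-sided but area velocity is
   negative at blink onset); the per-step threshold scales by
   `500/rate` at other rates.
3. **Detect**: maximal runs with `A_flat < 250` or `> 350`; runs closer
   than 20 ms are merged (bridging border flicker without joining
   distinct blinks). Both tails are treated as loss and the tail
   direction recorded — upward excursions are typically lash/mascara
   interference.
4. **Refine extent**: the smoothed absolute area velocity is walked
   outward from each loss bound while it exceeds a per-trial threshold
   (mean + 2.5 SD over samples ≥ 50 ms from any loss; floor 2 units/step),
   capped at 100 ms per side. The cap prevents runaway expansion on
   noiseless traces where the threshold floor engages.
5. **Categorize** by full duration: below 50 ms a dropout, 50–500 ms a
   blink, longer some other loss. The bounds are configurable; they are
   conventional blink-duration figures, not fitted values.

## Saccade detection

*Threshold.* Per trial, fixation-epoch samples with speed below a fixed
50 deg/s ceiling estimate the background noise; the detection threshold is
`max(20, mean + 2.5·SD)` deg/s. Noisy trials get higher thresholds; the
20 deg/s floor keeps fixational jitter out on quiet ones.

*Candidates.* Maximal supra-threshold runs lasting at least 10 ms
(5 samples at 500 Hz). Onset is the first sample of the run; offset the
first sub-threshold sample after it.

*PSO absorption.* A following event is absorbed into its predecessor when
it starts within 40 ms, its amplitude lies in 0.5–5°, and it is smaller
than the predecessor — iteratively, left to right. This trades duration
accuracy for endpoint accuracy: the absorbed endpoint sits at the settled
position rather than at the first oscillation extreme. Two deliberate
restrictions: the size test prevents chaining two genuine saccades, and
absorption never reaches across a data-loss interval, because an
oscillation is a signal property of the *tracked* pupil — events touching
loss belong to blincade resolution instead. The pre-absorption ("core")
offset and endpoint are retained on every record.

*Boomerang splitting.* Two opposed movements fused into one
supra-threshold event (usually an error toward the stimulus redirected
mid-flight) are detected on the core extent: initial and final 10 ms
directions more than 135° apart, each within 45° of one of the two
opposed task directions (and of different ones), and abnormal metrics —
path length over 1.5× the net amplitude, or duration over 1.5× a typical
main-sequence duration (2.2 ms/° × amplitude + 21 ms). The event splits at
the deepest speed nadir strictly between its two largest velocity lobes;
lobe identification requires the valley between the candidate peak and the
global peak to dip below half the smaller peak, so noise wiggles riding a
single lobe are never mistaken for bimodality. Criteria are evaluated on
the core extent because merged PSO lobes reverse the final-direction
estimate of perfectly ordinary saccades and inflate their durations; with
this choice the false-split count on slosh-affected ordinary saccades is
zero in the test battery.

*Blincades.* Events overlapping a loss interval are tagged: the gaze
displacement is real but its kinematics are not trustworthy. The classic
artefact — lid descent drags the apparent gaze up, loss, reacquisition
snaps it down — is resolved on upward-tagged events followed by a
movement that undoes at least half of the upward displacement: if the pair
returns to within 2° of its start it is recorded as a blink and removed
from the saccade table; otherwise it becomes a single blincade spanning
both events, usable for behaviour but excluded from kinematic statistics.
The pairing gap (40 ms) discounts time inside loss intervals, since full
loss of 50–150 ms always separates the pair on the wall clock. The
"downward" test is on the vertical return, not on total direction,
because a real ≥2° horizontal gaze change during the blink makes the
recovery movement diagonal.

*Main-sequence Z-scores.* Per block, peak velocity is fitted against
amplitude and against duration with penalized cubic smoothing splines
(`stats::smooth.spline`), constrained to at most 8 effective degrees of
freedom — enough to follow the saturating main-sequence shape, too stiff
to chase outliers; the realized degrees of freedom are recorded in the
fit object. Blincades, boomerang halves and records with missing metrics
are excluded from fitting (at least 30 clean saccades are required) but
every record is scored: `MaSeZs = residual / SD(clean residuals)`.
Downstream metric averaging keeps records with both |Z| below
`qnorm(0.9995) ≈ 3.29` (p < 0.001, two-sided); requiring *both* scores
below the cut is the conservative reading of an ambiguous rule, and the
policy is configurable.

## Pupillometry

The fixation-locked pupil response (constriction then dilation before the
predictable stimulus) is measured on *raw* area, in camera pixel counts —
all derived metrics are therefore homogeneous of degree one in the area
scale, which a test asserts. Eligibility: during fixation-plus-gap, no
saccade above 2°, mean gaze within 2° of fixation, and total loss below
200 ms. Baseline is the 150–200 ms post-fixation mean; the nadir and its
time are taken over non-lost samples only (never across interpolated
values — interpolation could fabricate a nadir); final size is the mean
over the 150–200 ms before stimulus onset. Response onset is the start of
the earliest 20 ms window (after 200 ms) in which every sample deviates
from baseline in the same direction by more than 1.96 baseline SDs — a
deterministic operationalization of "significantly differed" that needs
no distributional machinery beyond the stated window. Constriction and
dilation velocities are extrema of the 3-point-smoothed area derivative
in their respective intervals.

## Trial classification

Timing windows relative to stimulus onset: anticipatory −110 to 89 ms
(too early to be visually triggered), express 90–139 ms, regular
140–800 ms, late 800–1000 ms. Late saccades classify the trial but are
excluded from latency summaries; 1000 ms is the classification bound,
800 ms the metrics bound — both kept, roles separated.

The first *viable* saccade (amplitude ≥ 2°, launched within 2° of
fixation, onset in −110 to 1000 ms; blincades count, their behaviour being
real) sets the saccadic reaction time. The decision order is fixed so
rarer diagnoses cannot mask commoner ones: eye loss (more than half the
fixation-and-response epoch lost) → never fixated (no continuous 200 ms
within 2° of fixation) → fixation break (left the window before fixation
offset without return; a transient break with return sets a lapse flag
and the trial is defined by the subsequent behaviour) → anticipatory
correct/error by condition and direction → correct/error in the viable
window → random saccade (first movement more than 45° off both horizontal
task axes) → no saccade. Unresolvable trials are reserved as "Not
marked"; any single-trial failure degrades to that category rather than
aborting the session.

Session statistics keep two denominators deliberately apart: the
direction-error *rate* divides regular-window anti errors by all ANTI
trials; the *ratio* divides by correct-plus-error ANTI trials only. The
ratio therefore never falls below the rate, which is asserted as an
invariant. Non-compliance pools no-saccade, random-saccade and
never-fixated trials.

## The synthetic generator, and what the tests mean

`simulate_session()` builds sessions from behavioural archetypes (correct,
direction error, anticipatory, fused error-then-correct, fixation break,
no saccade, random, never fixated, eye loss) on the canonical IPAST
timeline, renders them to screen pixels through the configured geometry,
and records ground truth for every injected event. Defaults, chosen once
as typical of adult 500 Hz video recordings and of this task:

* main sequence `Vp = V∞(1 − e^{−A/A₀})` with `V∞ = 500` deg/s,
  `A₀ = 12°`; raised-cosine velocity profiles (duration `2A/Vp`);
* PSO: damped sinusoid at 20 Hz with 30 ms decay, amplitude
  `slosh_gain · (0.3 + 0.05·A)` degrees, along the saccade direction for
  horizontal movements;
* position noise 0.05° SD per axis; per-segment calibration offsets of
  0.1° SD;
* blinks: 30 ms area ramp to zero, 50–150 ms loss, 30 ms recovery,
  placed in the inter-trial interval (where participants typically blink)
  with a 300 ms refractory separation — overlapping blinks are physically
  impossible; the up/down gaze artefact is available but off by default
  (the blincade rule is exercised by constructed traces instead);
* pupil response: baseline 600 px², constriction 80 units reaching its
  nadir 600 ms after fixation onset, 40 units of re-dilation completing
  by 1100 ms, response onset 250 ms; area noise 0.5 px². The constriction
  approaches the nadir as a quarter-sine (non-zero initial velocity,
  smooth bottom).

Ground-truth event boundaries use a *measurable-motion convention*: a
commanded saccade "starts" and "ends" where its commanded speed crosses
the 20 deg/s detection floor, below which commanded motion is
indistinguishable from fixational noise. The same convention defines the
measurable amplitude (`measurable_amplitude()`), and the main-sequence
recovery check compares the fitted curve to the generative one on that
domain; comparing at commanded amplitude would charge the fit with the
~0.12° of sub-floor creep that no threshold detector can observe.

Problem sizes used by the test suite and the acceptance script: 100
default-condition trials for detection properties; 600 trials spanning
2–15° for the paired PSO-endpoint comparison and main-sequence recovery;
60 fused-pair and 320 ordinary-saccade trials for splitting; 1000 trials
for classification agreement; 230 quiet trials for pupil recovery; a
dozen constructed traces per blincade branch. These keep the full run in
a few minutes while leaving each estimate's sampling error well inside
the property margins — with one exception worth stating: the
main-sequence recovery error is typically 4–5% at its 5% margin. Its
systematic component is real measurement error, not fit error — ~2.5–3%
peak-velocity attenuation by the smoother plus PSO-endpoint displacement
(overshoot endpoints for oscillation lobes below the 0.5° absorption
floor, rebound-trough endpoints for absorbed ones) — and tightening it
further would mean changing the detector, not the spline.

Passing these checks shows the algorithms implement their definitions and
recover known structure under realistic noise. It does *not* show that
real data are this clean: real saccades have asymmetric velocity
profiles, real PSOs vary enormously between individuals (and the damped
sinusoid is only a first-order account), pupil foreshortening with gaze
eccentricity is not modelled, head motion and lighting changes are
absent, and the behavioural archetypes are unambiguous by construction —
real trials mix them. The classification agreement figure in particular
bounds algorithmic error, not disagreement with a human marker.

## Known limitations

* Absorbing PSOs deliberately overestimates saccade duration; duration
  consumers should use the core offset, also provided. Model-based
  separation of eye motion from iris slosh would recover both and is the
  natural next step.
* The smoothing-spline parameterization is package-specific; the
  effective-degrees-of-freedom cap (≤ 8) is the portable contract, and
  the realized value is recorded per fit.
* Saccades launched between fixation offset and the −110 ms anticipatory
  bound fall outside both the fixation-break and the viable windows;
  they are classified "No Saccade" if nothing follows. They are rare by
  design of the task; a dedicated category could be added if they turn
  out to matter.
* The ASC reader covers the sample/message subset of the vendor format
  that the pipeline uses; event tag strings are lab-specific and the
  regex map is configurable rather than guessed.
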
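---
title: "Spatiotemporal analysis of turning gait: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal analysis of turning gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turngait)
```

# The problem

When a person walks up to a pivot, turns through 90, 180 or 360 degrees
and walks on, the familiar straight-line gait parameters — speed,
cadence, stride and step length, stance and double-support times, stride
width — have to be redefined around the turn, separately for the leg on
the inside of the turn circle (internal) and the leg on the outside
(external). turngait implements that full chain from raw marker
trajectories: gait-event detection, turning-period segmentation,
parameter extraction, within-subject aggregation and Bayesian
repeated-measures inference on how walking speed (normal vs volitionally
slowed) and turning amplitude shape the parameters and their
trial-to-trial variability. Because motion-capture recordings of this
protocol are not freely redistributable, the package also contains a
first-class synthetic-trial generator with exact ground truth, so every
stage of the pipeline is testable end to end.

The marker set is minimal: bilateral heel (posterior calcaneus) and toe
(second metatarsal head) markers plus the four pelvis markers LASI,
RASI, LPSI and RPSI, sampled at 120 Hz. Internally everything is in
meters and seconds, z vertical, frame `f` at `t = f / rate`.

# The synthetic-trial generator

`gait_scenario()` + `generate_trial()` produce a walk–turn–walk trial:
a straight approach (default 5 m), a turn around a pivot, and a straight
exit (default 3 m).

**Pelvis.** The pelvis centroid traverses a smooth
straight–arc–straight path at the constant speed
`step_length / step_interval`, with its yaw locked to the path tangent;
the four pelvis markers ride a rigid rectangle (0.24 m between the
anterior markers, 0.10 m anteroposterior) around the centroid. The
total yaw change therefore equals the turn amplitude exactly, and the
yaw rate on the arc is `speed / turn_radius`.

**Footfalls.** Heel strikes occur every `step_interval` seconds,
alternating feet, with cumulative times rounded to the frame grid (so
individual intervals alternate by one frame around the target without
drift). Toe-offs follow each contact after
`stance_fraction x cycle`. Spatially, the feet are built as two
independent chains: each next same-leg contact is placed exactly
`2 x step_length` away in the plane, along the mean of the current and
previous step headings. The heading schedule is step-indexed: the turn
is executed over `round(arc / step_length)` steps, each rotating the
heading by an equal share of the amplitude. Placing contacts at equal
*planar* distance (equal chord) rather than equal *arc* length is a
deliberate choice: footfall-based gait analysis measures stride length
as the planar distance between consecutive same-leg contacts, and on
any arc tight enough to raise the pelvis yaw rate above the 30 deg/s
segmentation threshold the two definitions differ by several
centimeters. With the equal-chord construction the configured stride
length *is* the ground truth for what the pipeline measures, at every
amplitude.

**Feet during stance and swing.** The foot is a rigid heel–toe pair
0.20 m apart, exactly stationary and flat on the floor throughout
stance. Swing translates the heel to its next contact with a
fast-start sine profile (`sin(pi * phase / 2)`), so the foot
immediately outruns the pelvis after lift-off and settles with zero
horizontal velocity at contact, and lifts it with a half-sine of peak
0.05 m, so the vertical velocity is most negative exactly at contact.
These two profile choices make the classical event-detection extrema
coincide with the true contact and lift instants — the construction is
its own analytic oracle.

**Free parameters.** The protocol this emulates deliberately did not
constrain the turning path, so the turn radius is a free parameter. The
default is 1.0 m: small enough that the pelvis yaw rate on the arc
(about 65 deg/s at 1.13 m/s) clears the 30 deg/s threshold comfortably,
large enough that a 90-degree arc holds the required minimum of two
steps at normal step lengths (a 0.5 m radius would be rejected by that
rule for every realistic 90-degree scenario). A short standing lead-in
(two step intervals, realized by starting the pelvis 2 step lengths
behind the path origin) gives both feet a full initial stance, so even
the first toe-off is a physically detectable event.

**Cohorts.** `cohort_design()` / `generate_cohort()` draw per-trial
generator parameters as condition mean + subject random effect (one
draw per subject) + trial noise, mirroring the repeated-measures design
with a subject random intercept; each subject keeps one randomized turn
direction for all trials, as in the protocol. The default condition
means realize literature-reported operating points of the six speed x
amplitude cells — cadence 113/111/112 (normal 90/180/360) and 93/92/94
(slow), step lengths derived from the reference speeds
(`speed x 60 / cadence`), stance fractions from the reference
internal-leg stance/cycle ratios, and negative lateral offsets matching
the crossover sign of the external-leg stride width. Between- and
within-subject SDs default to the scale of literature-reported variability
table (e.g. 2.9 steps/min within-subject cadence SD). Defaults are
fixed once here and not tuned per analysis.

# Event detection

All detection runs in a pelvis-local progression frame
(`pelvis_frame()`): origin at the centroid of the four pelvis markers,
lateral axis from the right to the left anterior marker projected to
the ground plane, forward axis horizontal and orthogonal. A fixed lab
axis is meaningless through a 360-degree turn; the pelvis frame is not.

Signals are low-pass filtered with a zero-phase second-order
Butterworth run forward and backward (fourth-order response) at 6 Hz —
a standard choice for 120 Hz gait kinematics that the protocol itself
does not specify — and differentiated by central differences.
Candidate extrema need a prominence above 5% of the signal's
interquartile range (with a 1 micrometer absolute floor so that flat
signals yield no candidates) and are thinned by a refractory interval
of 0.4 x the median candidate spacing, keeping the earlier frame.

**Heel strikes** follow the foot-velocity principle: minima of the
filtered foot-center vertical velocity. Two guards make this robust
through turns: candidates must reach 30% of the signal's deep-descent
level (filter ripple during stance does not), and the foot's
over-ground velocity projected on the pelvis forward axis must drop
below 25% of its 95th percentile within 0.15 s of the candidate (a
landing foot stops; a mid-swing velocity wiggle does not). Each
candidate is then refined to the extremum of a lightly filtered (15 Hz)
velocity and snapped to the first frame at which the heel settles onto
its stance level. On noise-free synthetic trials this recovers every
event on the exact frame; with 1 mm marker noise, within 2 frames.

**Toe-offs** follow the coordinate principle: minima of the toe's
forward coordinate in the pelvis frame. During turning, the rotation of
the frame adds a drift term (yaw rate x lateral coordinate) that can
flatten the inner foot's minimum entirely — at realistic speeds the
rotation contribution approaches the translational one. The detector
therefore subtracts the accumulated rotation term from the coordinate
before the extremum search; in straight walking the correction is
identically zero and the rule reduces to the classical one. This is the
package's documented reconstruction of a turning-validated variant; it
is verified against the synthetic oracle, not against force plates.

Merged events are validated per side (heel-strike / toe-off
alternation; later duplicates dropped with a message), and fewer than
two heel strikes is an error, not an empty result.

# Turn segmentation and the analysis window

Pelvis yaw is unwrapped, filtered with the same 6 Hz convention, and
differentiated. The turning period is the longest contiguous run of
frames with |yaw rate| above 30 deg/s; runs shorter than 0.1 s are
ignored as noise, and the absolute value makes left and right turns
symmetric. The analysis window extends the period to the last toe-off
before its onset and the first heel strike after its offset. The turn
direction is the sign of the net yaw change over the run; the internal
leg is the leg on that side. Threshold clipping trims the shallow yaw
tails, so the measured amplitude is slightly below nominal (about 1–2
degrees at the defaults).

# Parameter conventions

Whole-turn parameters inside the closed window:

* `turn_duration` — window length.
* `n_steps` — the number of step intervals *spanning* the window:
  `1 + duration / tau`, where `tau` is the mean interval between the
  heel strikes inside the window. The window opens at a toe-off, so a
  swing phase with no heel strike always leads it; counting only the
  heel strikes strictly inside would undercount by almost one step and
  bias cadence low by roughly a quarter. The spanning convention
  reproduces the reported step counts (e.g. 3.75 steps for a 1.46 s
  normal-speed 90-degree window at cadence 113, where
  `1.46 x 113 / 60 + 1 = 3.75`) and makes the identity
  `cadence x duration / 60 + 1 = n_steps` hold exactly by construction.
* `cadence` — `60 / tau` steps/min.
* `speed` — horizontal arc length of the pelvis-centroid path across
  the window divided by the duration. Arc length, not net displacement:
  a 360-degree turn has near-zero displacement at a clearly nonzero
  walking speed.

Per-leg, per-cycle parameters are computed for every gait cycle whose
*starting* heel strike lies in the window; its completing heel strike
may fall just beyond the edge. A 90-degree window spans only 3–4 steps
while a cycle spans two, so demanding both ends strictly inside would
regularly leave the internal leg with no complete cycle at all. Cycle,
stance and initial double-support durations come from the event times;
stride length is the planar distance between the two footfalls (heel
position averaged over the 5 frames after contact, where the foot is
stationary); step length and signed stride width decompose the vector
from the preceding contralateral footfall along and across the chord
between the two contralateral footfalls bracketing the step. Width is
positive when the foot lands on its own anatomical side of that line
and negative for a crossover. The chord convention is isolated in one
function (`step_geometry`) and can be swapped; with it, stride widths
during tight turns carry a path-curvature component of up to a few
tens of centimeters on top of the foot-placement offset, and they are
the least faithfully emulated parameter family of the generator (real
turning data also shows strongly asymmetric internal/external widths).

Trials are aggregated in two stages: per-cycle values are averaged
within the trial, then the mean and the sample (n-1) standard deviation
are taken across a subject's trials — the within-subject SD is the
variability outcome. Condition tables report across-subject means with
percentile-bootstrap 95% CIs.

# Bayesian inference

For each response (a parameter's subject-level mean or within-subject
SD), `fit_turn_effects()` fits

```
value ~ speed * amplitude + (1 | subject),  Gaussian residuals
```

by MCMC: the fixed-effect and subject-intercept blocks are
conditionally conjugate and are Gibbs-sampled; the residual and
subject-intercept SDs take half-Cauchy(0, 2.5 x sd(y)) priors and move
by random-walk Metropolis on the log scale. Difference-coded
fixed effects have the conditional prior N(0, (1.6 sigma)^2), i.e.
N(0, 1.6^2) on the standardized effect — about 80% prior mass on effect
sizes between -2 and 2 — so a standardized contrast `c'beta / sigma`
has the scale-free prior N(0, (1.6 ||c||)^2) and the Savage–Dickey
density ratio at zero is well defined without reference to the response
units. The intercept prior is vague.

Inference outputs per contrast (slow-minus-normal at each amplitude,
pairwise amplitude differences within each speed, and the speed main
effect): the posterior mean difference with its 95% highest-density
interval, Cohen's d (`contrast / sigma`, scale-invariant), the
Savage–Dickey Bayes factor (kernel density with Silverman's bandwidth —
a documented tolerance source), the MAP-based p-value (posterior
density at zero over density at the mode), and the HDI+ROPE decision.
The region of practical equivalence is ±0.2 standard deviations of all
subject-condition values of the parameter, applied on the raw contrast
scale; the decision is `different` when the 95% HDI and the ROPE are
disjoint, `practically_equivalent` when the HDI sits inside the ROPE,
`undecided` otherwise. Variance-fraction eta squared per factor is
computed samplewise from the posterior cell means with the residual and
subject variance in the denominator, so a null simulation concentrates
near zero. No multiplicity correction is applied across parameters —
each response is modeled independently, by design.

Convergence is monitored by split-Rhat (flagged, never silent, above
1.01) and an autocorrelation-based effective sample size with Geyer
truncation; the pipeline notes when the ESS falls below 10,000 and the
chains should be lengthened for final reporting. Default chain lengths
in the package examples and tests (2 chains, a few hundred to ~1,500
kept draws) are sized for interactive use and test runs; report-grade
numbers warrant 10-fold longer chains, which the same seed-controlled
interface provides.

The decision operating characteristics under the study design (10
subjects, 2 x 3 cells) are checked by simulation in the test suite: on
null cohorts the rate of false `different` decisions stays below 10%,
and a standardized speed effect of d = 2 is declared `different` in at
least 80% of cohorts at reduced chain lengths.

# Worked example

```{r example, eval = FALSE}
sc <- gait_scenario(turn_amplitude = 90, step_interval = 60 / 113,
                    step_length = 0.600, stance_fraction = 0.6031)
trial <- generate_trial(sc)
analysis <- analyze_trial(trial$recording)
analysis$parameters[c("speed", "cadence", "stride_length_external",
                      "stance_ratio_internal")]

# a full synthetic study, end to end
res <- run_pipeline(run_config(out_dir = tempfile(), seed = 1,
                               n_subjects = 10, n_trials = 9))
```

# What passing tests do and do not show

The generator produces rigid, perfectly periodic gait: exact stance
stillness, noiseless or i.i.d.-Gaussian-noised markers, no marker
dropout or soft-tissue artifact, no step-to-step neuromotor
variability within a trial, stereotyped swing profiles, and a
one-parameter family of turn paths. Passing the recovery suites
therefore demonstrates that the pipeline's conventions are
self-consistent and that the detectors realize their defining extrema
exactly under their stated assumptions — not that the detectors would
achieve frame-exact timing on real marker data, where validation
against force plates or instrumented walkways would be required.
Numbers carried over from reference condition means from the turning-gait literature (cadences,
speeds, stance ratios, stride lengths and variability scales) make the
synthetic cohorts realistic operating points; they do not make the
synthetic data a substitute for the original recordings, and posterior
summaries from synthetic cohorts are not expected to reproduce the
original study's posteriors.

Other known limitations: turning strategy is not sub-classified
(step turn vs spin turn); phase-resolved analysis within the turn is
out of scope; stride-width emulation during tight turns is dominated by
path geometry, as discussed above; and C3D files are not parsed — TRC
or the documented CSV layout are the interchange formats.
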
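---
title: "Separating the control of moving and holding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating the control of moving and holding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveholdlab)
```

## The scientific question

After a stroke, the paretic arm shows two superficially similar but possibly
distinct abnormalities: it rests in an abnormal, typically flexed posture, and
it moves poorly. `moveholdlab` implements an analysis pipeline that separates
the two. The resting abnormality is quantified as a **resting postural force
bias**: the force the hand involuntarily exerts on a robot handle while the
participant is told to relax, measured at many positions of a planar
workspace. The movement abnormality is quantified from 10 cm point-to-point
reaches over a five-target array, from responses to brief lateral force
pulses during those reaches, and from responses to the abrupt release of a
sustained holding force after the reach has ended. The central question is
whether the resting bias field *intrudes* on active movement (it should, if
moving and holding share one controller) or only re-emerges once the movement
is over (as expected if they are separable control modes).

The package answers this with three statistical instruments:

* **extreme-instance contrasts** — for each participant, the two movement
  directions (or position x release-direction combinations) where the
  projected resting bias is most opposed vs. most aligned with the relevant
  perturbation, compared with a paired t-test;
* **per-subject sensitivity regressions** — the OLS slope of each outcome
  against the projected resting bias over all trials, with a one-sample
  t-test of the per-subject slopes against zero;
* the **Response Asymmetry Index**, `RAI = (r_A - r_O) / (r_A + r_O)`, where
  `r_A` and `r_O` are the response magnitudes in the most-aligned and
  most-opposed instances. The RAI cancels overall response scale, so the
  asymmetry induced by the resting bias can be compared across perturbation
  types (holding release vs. moving pulse).

## Coordinates, signs and event rules

All internal mathematics uses +x rightward, +y away from the body, forces as
participant-on-handle, angles in degrees with 0 at "3 o'clock" and CCW
positive, wrapped to (-180, 180]. Left-arm trials are mirrored about the
y-axis (`flip_left_to_right()`) before pooling: x and fx negate, CW/CCW pulse
labels swap, release directions mirror.

Event detection uses the standard velocity-threshold rules:

* movement onset: speed first exceeds 3.5 cm/s;
* movement end: within 0.5 cm of the target (half the 10 mm target diameter)
  at speed below 3.5 cm/s;
* initial angle `theta_start`: signed deviation of the chord from onset to
  onset + 150 ms relative to the start-to-target direction; endpoint angle
  `theta_end`: the same for the chord starting at the first crossing within
  2 cm of the target; trials with `|theta_start| >= 90` degrees are outliers;
* pulse settling: absolute lateral velocity below 2 cm/s sustained for
  100 ms (censored at movement end); maximum lateral deviation is taken
  between pulse onset and movement end, signed along the pulse;
* release stabilization: speed below 2 cm/s sustained for 100 ms while
  within 2 cm of the target; trials that do not stabilize inside the recorded
  window are excluded, imputed at 2.0 s, or left uncapped (`cap_mode`).

Persistence ("sustained for 100 ms") is evaluated on the closed window
[t, t + 0.1 s]: every sample recorded in that window must satisfy the
criterion, and the window must be fully recorded. At exactly 200 Hz this is
21 samples. Velocity is estimated by central differences with a 25 ms moving
average; the smoothing default was chosen so that threshold crossings on
minimum-jerk profiles move by at most one sample (verified by test). Because
no differentiation scheme is canonical, event times on real recordings may
differ from other implementations by a few milliseconds.

Resting biases are the mean handle force over the last 3 s of each 5 s
passive hold ([2, 5] s after hold onset), skipping the first 2 s over which
approach-velocity effects dissipate. Visits to the same position are
averaged; the five canonical target forces are filled by direct lookup
(within 0.5 cm) or by piecewise-linear interpolation on a Delaunay
triangulation of the measured positions (exact on linear fields; queries
outside the hull fall back to the nearest measurement and are tagged).

Trial rejection in the original workflow was by visual inspection; the
package replaces it with an automated proxy (`qc = "auto"`): a trial is
flagged when the hand moves more than 1 cm during the hold or when the
within-window force SD exceeds 3x the sensor noise scale. Both analysis
modes (with and without rejection) are exposed because robustness to the
rejection rule is part of the analysis contract.

## The release projection sign

`project_bias()` returns, for the release context, the component of the bias
along the *displacement* direction (opposite the removed force): positive
means the bias pushes the hand the way the release perturbation will throw
it. The sensitivity regressions and extreme selections for that context use
the **resistive** component (its negative), so that — as in the headline
result — *negative* slopes mean better performance (shorter stabilization,
smaller deviation) when the resting bias resists the perturbation.

## The scalar potential (isocline) map

`fit_potential()` reconstructs a scalar field `phi` whose negative gradient
approximates the interpolated bias field, by regularized least squares on a
regular grid: centered-difference gradients, a small Laplacian penalty
(`lambda = 1e-3`), and the gauge fixed so `phi = 0` at the node nearest the
center target. Level sets of `phi` are the isoclines that bias vectors cross
perpendicularly, pointing downhill. The RMS of `grad(phi) + F` is reported as
`fit_residual`; for a rotational (curl) field, essentially all field energy
stays in the residual, which is the honest way to report a non-conservative
component rather than silently absorbing it.

## The synthetic cohort generator

Every stage is verifiable without data downloads because the `synthetic`
module generates full cohorts with known ground truth. The generator is a
model of the *study conditions*, not a claim about patients' physiology:

* **Bias field** — a convergent field pointing from each hand position
  toward a near-body attractor (default `(0, -15)` cm, below the center
  target), with magnitude `impairment * distance_gain * d` growing with
  distance `d` from the attractor, halved under arm support
  (`support_scale = 0.5`). With `distance_gain = 0.32` N/cm a fully impaired
  arm produces ~6.5 N at the distant targets and ~3.4 N at the near targets
  unsupported — the magnitudes reported for severely affected arms. A
  nominal FM-UE score is attached by the affine rule `66 - 52 * impairment`.
* **Gating** — the defining feature: `hold_only` turns the bias off during
  movement and ramps it on (`ramp_tau = 0.3` s) after movement end, detected
  online with the same rule the analysis uses; `always_on` is the
  counterfactual in which resting posture contaminates movement; `off`
  removes the bias.
* **Arm dynamics** — a planar point mass (2 kg, damping 0.1 N.s/cm) driven
  by a PD servo (stiffness 4 N/cm, damping 0.35 N.s/cm in the unimpaired
  default) tracking a minimum-jerk reference. Impairment slows the reference
  (`+0.6 s` per unit impairment), lowers stiffness (-40%) and damping
  (-70%, producing the underdamped, oscillatory corrections seen in paretic
  responses).
* **Holding controller** — after movement end the servo drops to half
  stiffness (`hold_kp_frac = 0.5`) and a leaky reference adaptation
  (rate 1 /s, leak 2.5 s; rate reduced by impairment) gradually absorbs
  static loads. This is what produces the release-perturbation
  phenomenology: the sustained 6 N load is mostly absorbed while holding, so
  its abrupt release throws the hand the opposite way; the finite leak means
  the resting bias is only partially absorbed and re-expresses during the
  recovery. These constants were calibrated so the simulated paretic release
  responses match the reported scale of the originals (~2-4 cm maximum
  deviation against the 2 cm stabilization radius, ~0.6-1 s stabilization
  times, a small fraction of trials hitting a 2 s recording cap).
* **Noise** — white sensor force noise (0.3 N per 200 Hz sample), white
  motor noise (0.6 N at the 1 kHz simulation rate), and a slow
  visit-to-visit fluctuation of the expressed bias (0.6 N per component at
  full impairment, scaled like the field). The visit fluctuation is what
  makes repeated measurements at one position disagree by more than sensor
  noise, so that the measurement-variance decomposition has something real
  to measure.
* **Perturbations** — the 70 ms lateral pulse is a raised cosine with 12 N
  peak (a smooth, compactly supported "bell" with the closed-form impulse
  12 x 0.070 / 2 = 0.42 N.s), triggered at 2 cm progress; the release is a
  linear 2 s ramp to 6 N along one of 45/135/225/315 degrees, held for a
  uniform 3-5 s, then stepped to zero, with recording retained for 2 s after
  release (so a capped-trial fraction arises naturally).
* **Protocol** — passive-hold blocks visit 15-25 positions three times each
  per arm x support condition (positions chained, approached by 5 s passive
  minimum-jerk moves, held 5 s); reach blocks follow the 96-movement
  composition: 12 movements in each of 8 directions over the 5-target array,
  64 unperturbed / 16 CW / 16 CCW pulses, and exactly one extended-hold
  release per (position, direction) pair. Because the trial-type vocabulary
  is exclusive, release trials are drawn from the unperturbed movements.
  The five targets sit at the center and 10 cm away at 45, 135, 225 and 315
  degrees; "distant" = center + the two upper targets, "near" = the two
  lower ones.

Integration is fixed-step RK4 at 1 kHz, downsampled to the 200 Hz recording
rate, with the noise sequence drawn from R's RNG so cohorts are bit-identical
under a seed across platforms.

What the generator does **not** emulate: joint-space/muscle dynamics, EMG,
reflex loops with delays, visual feedback corrections, fatigue or learning
across blocks, and any nonstationarity of the bias beyond the per-visit
fluctuation. Passing tests therefore demonstrate that the *pipeline*
recovers the truth of this generative model under realistic noise — not that
the model is the truth of any patient.

## What the discrimination tests establish

Under `hold_only` gating the movement-phase outcomes (initial angle, pulse
settling, pulse deviation) are, by construction, statistically independent of
the resting bias, so their sensitivity t-statistics follow a null t
distribution — the suite checks |t| < 2 across seeded replicates. The
endpoint angle is deliberately excluded from that null set: its 150 ms chord
can overlap the first moments after movement end, where the gated bias is
already ramping on, so in the simulator it is not a pure movement-phase
probe. Release-context sensitivities must come out significantly negative,
and the holding RAI must exceed the pulse RAI. Under `always_on` the
initial-angle sensitivity becomes significantly nonzero; its *sign* is not
asserted a priori but checked against an independent integration of the same
arm model with `deSolve` (a servo equilibrates against a constant force, so
the net deflection depends on how the field varies along the path, not just
on the bias at the start — the oracle captures this).

Problem sizes for these checks (the package's own choice, balancing
statistical power against suite runtime): per replicate, 16 hold-only
subjects spanning impairments 0.25-1, one supported paretic passive-hold
block of 9 positions x 3 visits, and one 96-movement reach block; 20
replicates; one additional always-on cohort. The recovery check uses 6
subjects with the full 4-block passive-hold protocol (15 positions x 3
visits).

## Numerical choices and degenerate inputs

* Persistence windows on closed intervals; events at sample resolution.
* The Delaunay triangulation is a plain Bowyer-Watson implementation
  (15-25 points); collinear position sets are an error, and maps with fewer
  than three positions fall back to nearest-measurement canonical forces.
* Extreme-instance ties are broken lexicographically by direction key, so
  symmetric synthetic fields select deterministically.
* The one-sample t-test of sensitivity slopes guards exact-zero spread
  (slopes all equal) and reports t = 0 / p = 1 or a zero-variance error for
  paired contrasts with exactly tied differences.
* Classical eta squared (`SS_effect / SS_total`, all strata pooled) is the
  default effect size of the resting-magnitude ANOVA; partial eta squared is
  reported alongside. The model is `aov` with Support and Proximity within
  subject, FM-UE as a continuous between-subject covariate, all two-way
  interactions, and `Error(subject)`.
* Two-sided p-values, no multiple-testing correction, matching the original
  reporting convention.

## Limitations

The simulator's linear servo washes out constant-force intrusion during
steady tracking (a constant bias shifts the equilibrium rather than the
direction of travel), so the always-on counterfactual produces
geometry-dependent angle effects rather than a simple "deflection along the
bias". Real arms are nonlinear and time-varying; the discrimination logic —
null movement-phase sensitivities, negative release sensitivities, RAI
ordering — is the portable conclusion, not the particular effect sizes. The
automated QC proxy is a reproducible stand-in for visual inspection, not a
replication of it; both QC modes should be run on real data. The variance
decomposition implements one defensible reading (within-position sum of
squares over total, on bias magnitudes); other readings exist, and the
fraction should be re-derived before comparing against any published value.
At the default visit-fluctuation level the synthetic fraction is of order 1%
of total variance — real recordings show substantially more repeated-
measurement variability, so treat the synthetic fraction as a mechanism
check, not a calibration.
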
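# moveholdlab

Tools for separating the control of *moving* from the control of *holding*
in planar robotic-manipulandum experiments on post-stroke arm paresis.

After a stroke, the arm both rests abnormally (a flexed posture that shows up
as an involuntary **resting force bias** on a robot handle) and moves
abnormally. Whether the resting abnormality contaminates active movement is a
core question for both motor-control theory and rehabilitation.
`moveholdlab` implements the complete analysis that answers it:

* **Resting bias fields** (Experiment-1 style passive-hold trials): per-trial
  bias estimation over the last 3 s of each 5 s hold, per-position averaging
  across visits, piecewise-linear interpolation at the canonical 5-target
  array, magnitude/direction summaries (circular statistics for directions),
  a scalar-potential ("isocline") reconstruction of the field, and a
  variance decomposition quantifying measurement repeatability.
* **Reaching and perturbation kinematics** (Experiment-2 style reach
  trials): velocity-threshold movement onset/end (3.5 cm/s; 0.5 cm target
  radius), initial and endpoint reach angles over 150 ms chords, path
  lengths, pulse-perturbation settling time and lateral deviation, and
  release-perturbation stabilization metrics (2 cm/s for 100 ms within 2 cm
  of the target), with the standard outlier and censoring rules.
* **Interaction statistics**: projection of resting biases onto movement and
  perturbation geometry, extreme-instance paired contrasts, per-subject
  sensitivity regressions, a mixed ANOVA of bias magnitudes against
  impairment (FM-UE), proximity and arm support, and the Response Asymmetry
  Index

  `RAI = (r_A - r_O) / (r_A + r_O)`

  which compares response magnitudes when the resting bias is aligned
  (`r_A`) vs. opposed (`r_O`) to a perturbation, on a scale-free footing.
* **A synthetic cohort generator**: a planar point-mass arm with a PD reach
  servo, a leaky-adaptation holding controller, and a convergent resting
  bias field whose gating is the scientific knob — `hold_only` (bias off
  during movement, ramping on after movement end) vs. `always_on` — with
  full ground truth, so the whole pipeline is verifiable end to end.

## Worked example

```r
library(moveholdlab)

subjects <- data.frame(
  subject_id = sprintf("P%02d", 1:6), group = "patient", side = "right",
  impairment = seq(0.4, 1, length.out = 6), gating = "hold_only")
cfg <- cohort_config(subjects, n_positions = 9, visits = 3, exp2_blocks = 2,
                     exp1_arms = "paretic", exp1_supports = "airsled",
                     exp2_arms = "paretic")
run <- run_pipeline(run_config(seed = 7, cohort = cfg))

rest <- run$rest$summary$group
rest[, c("arm", "support", "mag_distant", "mag_near", "dir_deg")]
#>       arm support mag_distant mag_near   dir_deg
#> 1 paretic airsled    2.287065 1.189444 -89.96721

s <- run$hold$sensitivities
round(c(theta_start_p = s$theta_start$p, release_time_p = s$release_time$p,
        release_dev_p = s$release_max_dev$p), 5)
#>  theta_start_p release_time_p  release_dev_p 
#>        0.05765        0.00499        0.00027
```

The bias map shows the signature geometry: supported paretic biases of
~2.3 N at the distant targets vs. ~1.2 N at the near ones, pointing toward
the body (about -90 degrees). The initial-reach-angle sensitivity to the
resting bias is not significant (p = 0.058: no evidence that the bias
deflects the early reach), while both release-perturbation outcomes are
significantly modulated by it (time to stabilization p = 0.005 at
-0.11 s/N; maximum deviation p = 0.0003 at -0.29 cm/N — negative slopes:
recovery is faster and smaller when the resting bias resists the
perturbation). Holding, not moving, expresses the resting abnormality.

Real recordings are read and written through a plain manifest format
(`read_trialset()` / `write_trialset()`): a JSON manifest plus one CSV per
trial with columns `t,x,y,fx,fy` (s, cm, N).

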
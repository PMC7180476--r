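# gaitwarp

Template-based detection of gait events in single-axis gyrometer signals,
with Dynamic Time Warping (DTW) boundary refinement.

## The problem

Clinical gait analysis needs the start and end of every stance phase — the
Initial Contact (IC, heel strike) and Final Contact (FC, toe off) — from
body-worn inertial sensors. The sagittal-plane (y-axis) angular velocity of
a foot-mounted gyrometer traces a highly stereotyped waveform over each
stance: a brief positive deflection at heel strike, a deep negative loading
peak, a flat mid-stance plateau, and a second negative excursion at toe
off. Step durations and speeds, however, differ between subjects and
between strides, and the deformation from one stance to another is
*non-linear* in time: individual gait phases stretch and shrink
independently. Detectors based on thresholds or purely linear template
correlation must therefore either carry many templates or accept biased
event times.

`gaitwarp` implements a two-stage detector that needs as little as a single
template:

1. **Greedy template matching.** For every template `p` of length `L`, the
   Pearson correlation between `p` and each signal window
   `x[t : t+L-1]` is computed. Strict local maxima above a threshold
   (default 0.7) form a candidate pool across all templates; candidates are
   accepted in decreasing correlation order whenever their window does not
   overlap an already accepted detection. Each accepted detection has
   provisional boundaries `[t_IC, t_FC]` with `t_FC - t_IC + 1 = L`.

2. **DTW refinement.** Around each detection, all lag pairs
   `(k, l) ∈ [-z, z]²` are scanned and

   `(k*, l*) = argmin DTW(x[t_IC+k : t_FC+l], p)`

   gives the refined boundaries `t_IC* = t_IC + k*`, `t_FC* = t_FC + l*`
   (defaults `z = 10` samples, i.e. 100 ms at 100 Hz). The DTW distance is
   the minimal cumulative cost over monotone, boundary-anchored warping
   paths restricted to a Sakoe–Chiba band `|i - j| ≤ maxsamp` (default
   20 samples), with the z-normalised pointwise cost

   `d(u_i, v_j) = ((u_i - ū)/σ_u - (v_j - v̄)/σ_v)²`

   which makes the match invariant to amplitude scale and offset.

Five strategies build the template library from an annotated step
collection: **S1** random selection, **S2** the DTW medoid
(`argmin_s Σ_n DTW(s, s(n))`), **S3** linear fusion (z-normalise, linearly
resample to the median stance length, average), **S4** non-linear fusion
(DTW-align all steps onto a medoid calibration step, then average), and
**S5** a knowledge-based piecewise-affine prototype built directly from the
biomechanical landmarks (63 samples, mid-stance plateau at 0.8).

Detections are scored against annotations with event-level metrics:
precision and recall under a one-to-one midpoint rule, and the absolute
timing errors ΔStart, ΔEnd and ΔDuration in milliseconds. A seeded
synthetic-cohort generator with exact ground truth makes the whole pipeline
testable end to end.

## Worked example

```r
library(gaitwarp)

cohort   <- synth_cohort(synth_params(n_trials = 4, steps_per_trial = 6, seed = 42))
template <- strategy_piecewise()      # S5: the knowledge-based prototype
template
#> <step_template> S5:analytic (S5, source analytic): 63 samples in [-2.6, 0.8]

det <- detect_and_refine(cohort$trials[["trial01"]],
                         template_library(template), detector_config())
det
#> # A tibble: 6 × 7
#>   step_id    ic    fc template_id correlation dtw_cost refined
#>     <int> <int> <int> <chr>             <dbl>    <dbl> <lgl>
#> 1       1    47   107 S5:analytic       0.979   0.792  TRUE
#> 2       2   160   218 S5:analytic       0.959   0.253  TRUE
#> 3       3   271   329 S5:analytic       0.954   0.355  TRUE
#> 4       4   361   421 S5:analytic       0.973   0.157  TRUE
#> 5       5   461   523 S5:analytic       0.999   0.0678 TRUE
#> 6       6   568   629 S5:analytic       0.986   0.201  TRUE

report <- evaluate_detections(det,
  dplyr::filter(cohort$annotations, trial_id == "trial01"))
report
#> <eval_report> precision 1.000, recall 1.000 (6/6 detections correct, 6 annotations)
#>   |dStart| 0.0 (0.0) ms, |dEnd| 0.0 (0.0) ms, |dDuration| 0.0 (0.0) ms
```

Each detection row is one stance: `ic`/`fc` are the refined IC/FC sample
indices (1-based, inclusive), `correlation` the matching-stage Pearson
peak, and `dtw_cost` the refined cumulative DTW distance to the template.
On this low-noise synthetic trial every annotated stance is recovered with
zero timing error.

Experiment runners reproduce the standard analyses on synthetic cohorts:
`run_experiment_1()` (effect of DTW refinement for random templates),
`run_experiment_2()` (strategy comparison), `run_experiment_3()` (error
versus scan half-width `z`), `run_experiment_4()` (DTW versus Pearson
refinement criterion). `tidy()`, `glance()` and `autoplot()` methods are
provided throughout, and `inst/scripts/gaitdtw.R` exposes
`simulate` / `build-template` / `detect` / `evaluate` / `dtw-dist` /
`experiment` subcommands for shell use.

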
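---
title: "Methods: template matching and DTW refinement for gait event detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template matching and DTW refinement for gait event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwarp)
```

## The model

A walking trial recorded by a foot-mounted gyrometer is, on its sagittal
(y) axis, a sequence of stereotyped stance waveforms separated by
quiescent swing segments. `gaitwarp` models each stance as a non-linearly
time-warped, amplitude-scaled, offset and noise-corrupted instance of a
prototype waveform, and detects the stance intervals `[ic, fc]` (Initial
Contact to Final Contact, 1-based inclusive sample indices, so the
duration is `fc - ic + 1` samples) in two stages.

**Stage 1 — greedy correlation matching.** For each template `p` of
length `L`, the Pearson coefficient between `p` and every signal window of
length `L` is computed with rolling sums. Candidate placements are the
strict local maxima of these profiles (greater than both neighbours;
profile endpoints are never candidates) exceeding the correlation
threshold, pooled across templates. Candidates are visited in decreasing
correlation order and accepted if their window does not overlap an
already-accepted detection. Pearson correlation is invariant to amplitude
scale and offset but *not* to duration changes: a detection's provisional
interval always has exactly the template's length, which is the stage's
built-in bias.

**Stage 2 — DTW refinement.** Around each provisional detection all
`(2z + 1)^2` lag pairs `(k, l)` in `[-z, z]^2` are scanned; the refined
boundaries are the lag minimising the DTW distance between the shifted
window and the generating template. The end boundary moves by the end lag
`l*` and the start boundary by the start lag `k*`. Lags whose window
leaves the signal, has fewer than two samples, is constant, or whose
length differs from the template's by more than the band half-width are
skipped rather than clamped — clamping would silently change the window
length being scored.

**The DTW engine.** The distance between series `u` and `v` is the
minimal cumulative cost over warping paths that start at `(1, 1)`, end at
`(N_u, N_v)`, advance by `(1,1)`, `(1,0)` or `(0,1)` (the classic
symmetric, unweighted step pattern), and stay inside the band
`|i - j| <= maxsamp`. The pointwise cost is the squared difference of the
*series-level* z-scores: means and standard deviations are computed once
over each whole input series (population divisor `N`), not per window or
per pair. This makes the distance exactly invariant to positive affine
amplitude maps of either series.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `correlation_threshold` | 0.7 | – | minimum Pearson peak height accepted in stage 1 |
| `z` | 10 | samples | refinement scan half-width (100 ms at 100 Hz) |
| `maxsamp` | 20 | samples | DTW band half-width (200 ms at 100 Hz) |
| `min_peak_separation` | 0 | samples | optional thinning of per-template peaks |

The threshold is the silent parameter of the matching stage: 0.7 is low
enough to admit strongly warped stances (whose linear correlation with a
fixed-length template degrades) and high enough that smooth low-amplitude
swing noise essentially never crosses it over a template-length window.
`z = 10` with `maxsamp = 20` is the self-consistent pairing: the extreme
scan lags `(k, l) = (-z, +z)` change the window length by `2z`, which is
feasible exactly when `2z <= maxsamp`. The band is enforced *inclusively*
(`|i - j| <= maxsamp`) for this reason; with a strict inequality the
corner lags of the default scan would be infeasible. When a user sets
`2z > maxsamp`, the configuration warns and the scan skips the infeasible
corners.

## Numerical choices

* **Cumulative, not length-normalised, cost.** The DTW distance is a plain
  sum along the path. In the refinement scan this slightly favours
  shorter windows (fewer terms); it is kept because it is the standard
  definition, and the bias is bounded by the per-sample cost of the
  template's edges, which are steep for stance waveforms. The
  scan-half-width experiment (`run_experiment_3()`) makes the resulting
  error-versus-`z` trade-off visible.
* **Tie-breaks.** DP predecessors: diagonal, then vertical, then
  horizontal — the backtracked path is unique and reproducible. Refinement
  argmin: smallest `|k| + |l|`, then lexicographic `(k, l)` — the least
  perturbation wins. Medoid ties: lexicographically smallest step id, so
  the S2/S4 strategies are invariant to collection order.
* **Degenerate inputs.** Constant series cannot be z-normalised and raise
  a typed error; constant windows in the correlation profile are flagged
  and given correlation 0; constant windows in the refinement scan are
  skipped.
* **Infeasibility.** `|N_u - N_v| > maxsamp` admits no path and raises a
  distinct error class, so callers can tell infeasibility from degeneracy.
* **Indexing.** All indices are 1-based and stance intervals inclusive at
  both ends, the natural R convention; files written by the package record
  `index_base: 1` in their comment headers.

## Template strategies

* **S1 (random)** draws `n` raw steps uniformly without replacement,
  reproducibly from a seed; the selected ids are reported so their source
  trials can be held out of a test set. S1/S2 templates are stored
  unnormalised: the matcher is scale-invariant and the DTW distance
  re-normalises internally, so normalising them would only discard
  provenance.
* **S2 (DTW medoid)** minimises the row sum of the pairwise DTW matrix
  (the candidate's zero self-distance included — a harmless constant).
* **S3 (linear fusion)** z-normalises, linearly resamples every step to
  the collection's median length (for an even count, the lower middle
  value) and averages. The average of z-normalised steps is itself not
  exactly unit-variance; it is kept as produced.
* **S4 (non-linear fusion)** picks, among steps of exactly the median
  length, the one with minimal mean DTW distance to all steps as the
  calibration step, warps every step onto its time base (each calibration
  sample receives the mean of the step samples matched to it on the
  optimal path), and averages. When no step has exactly the median length
  — possible on small synthetic collections — the candidates are the
  closest lengths, ties to the shorter; a real step database always
  contains the median length.
* **S5 (knowledge-based)** is a 63-sample piecewise-affine idealisation of
  the stance waveform, continuous at its five interior breakpoints, with
  the mid-stance plateau at 0.8 and the toe-off minimum at -2.6 in
  dimensionless normalised-amplitude units (the detector is scale
  invariant, so the units drop out). For lengths other than 63 the
  generating function is evaluated on a uniformly rescaled abscissa.

## Evaluation metrics

A detection is *correct* if the mean of its start and end indices lies
inside an annotated stance (endpoints inclusive; midpoints compared as
reals, so half-integer midpoints cause no parity artefacts). Each
annotation can be used once; among several detections inside one
annotation the midpoint-closest survives, ties to the earlier detection.
Precision is correct detections over all detections. Recall uses the
symmetric rule — annotation midpoints inside detected intervals, each
detection usable once. ΔStart, ΔEnd and ΔDuration are reported as mean
(SD) of the *absolute* errors in milliseconds
(`ms = samples * 1000 / rate`); signed errors are retained alongside for
diagnosing systematic bias. With no detections precision is undefined and
reported as `NA` rather than 0.

## The synthetic generator

Real annotated gyrometer databases are not redistributable, so the
generator emulates the statistical structure the detector assumes, with
exact ground truth by construction: ~100 Hz sampling, 8 stances per trial,
stance durations from a symmetric discretised law (median + centred
binomial, default median 63 samples, spread ±6) so the cohort median
equals the configured median exactly; swing segments of 30–54 samples
(stance ≈ 60 % of the cycle) filled with smoothed low-variance noise
rather than a biomechanical swing model, since only stance is detected;
per-subject duration offsets and amplitude factors; within-step monotone
random warps bounded by `warp_intensity` (default 8 ≤ `maxsamp`, so the
generative model stays inside the detector's band); uniform amplitude
scaling (0.8–1.25), baseline offsets, and white noise (default SD 0.05
against a prototype peak-to-peak of 3.4).

The warp duplicates (or, for shortened stances, skips) individual
prototype samples along a monotone map with bounded deviation from the
diagonal. One consequence worth noting: duplication perturbs the warped
series' own mean and standard deviation, so the z-normalised DTW distance
between a noiseless warped stance and the prototype is *small but not
exactly zero*; tests assert near-zero accordingly.

What passing tests on this generator do **not** show: robustness to real
sensor artefacts (drift, saturation, re-calibration), turning or
non-straight walking, pathological or elderly gait, or the detailed swing
dynamics — the swing model is deliberately featureless. Results on the
synthetic cohorts demonstrate internal consistency of the method, not
clinical performance.

## Experiment runners and problem sizes

The four runners mirror the standard analyses: refinement on/off for
random templates (E1, with training trials held out of the test set and
per-step errors concatenated across the 20 template draws), learned-
strategy comparison (E2), error versus scan half-width (E3, sharing one
set of initial detections across all `z`), and DTW versus Pearson
refinement (E4, both criteria applied to the *same* initial detections so
the per-step differences are paired). Absolute error magnitudes on
synthetic cohorts are generator-specific; the scientifically meaningful
outputs are the directions (refinement helps a single template; DTW beats
a linear criterion only under non-linear warps) and these are what the
test suite asserts.

The default validation cohort is 20 trials × 8 steps (160 stances), which
keeps every end-to-end analysis comfortably interactive while being large
enough that precision/recall of 1.0 is informative.

```{r example, eval = FALSE}
cohort <- synth_cohort(synth_params(seed = 42))
e1 <- run_experiment_1(cohort, sizes = 1, n_simulations = 20, seed = 7)
tidy(e1)
autoplot(run_experiment_3(cohort, z_values = 1:20))
```

## Known limitations

* Cumulative (unnormalised) refinement cost biases slightly toward short
  windows, visible as 1-sample boundary errors when warps duplicate edge
  samples.
* The greedy matcher enforces non-overlap, but refinement may re-introduce
  small overlaps between adjacent detections; they are permitted and
  counted in the `"n_overlaps"` attribute rather than resolved, since the
  evaluation's one-to-one midpoint matching already handles them.
* Single-axis input only; no multi-scale template pyramid; no streaming
  operation. Templates longer than a trial are rejected, not truncated.
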
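---
title: "Boundary coding in navigation behavior and BOLD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary coding in navigation behavior and BOLD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundnav)
```

`boundnav` analyses a virtual object-location memory task: participants
navigate a square arena, recall the locations of three objects placed at
different distances from the walls, and (in the scanner) their BOLD signal
is modeled as a function of moment-to-moment boundary distance. This
vignette documents the models the package implements, the assumptions
behind them, the tunable parameters, and the design decisions taken where
the problem was genuinely open. No empirical claim is made here beyond what
the package's own tests and simulations compute.

## Arena geometry and wall-distance conventions

The arena is the square `[0, L]^2` with `L = 160` vm, the origin at a
corner. This convention is forced by the registered target coordinates:
with walls at 0 and 160 on each axis, the trash bin (33, 16), plant
(27, 69) and ball (64, 38) have summed two-wall distances 49, 96 and
102 vm, which is exactly how the targets grade boundary proximity.

Three distance functions are provided, all continuous (no grid):

* `axis_wall_distance()` — `min(c, L - c)` for one axis coordinate;
* `two_wall_distance_sum()` — the x- and y-axis distances summed; maximal
  (`= L`) only at the arena center. This is the primary measure, on the
  rationale that navigators are influenced by several walls at once;
* `nearest_wall_distance()` — the single closest wall, used for
  robustness variants.

Positions exactly on a wall are legal (distance 0); positions outside the
arena are rejected at ingest, naming the offending coordinate. Where a
wall distance appears in a denominator (bias, BPI) it is clamped at
0.1 vm — an arbitrary but fixed floor, chosen small relative to any
behaviorally meaningful distance — and every clamp event is warned about
with a count, so silent degeneracy cannot occur.

## The navigation agent

The synthetic agent reproduces the task's kinematics exactly: translation
at a constant 15 vm/s, rotation in place at 50 deg/s, and no translation
during rotation, so every path is a chain of straight constant-speed
segments. Trajectories are sampled on a regular grid.

Parameters of `agent_params()`, with units and defaults:

| parameter | unit | default | role |
|---|---|---|---|
| `translation_speed` | vm/s | 15 | task constant |
| `rotation_speed` | deg/s | 50 | task constant |
| `sampling_rate` | Hz | 10 | trajectory grid; fine enough that a 1.5-s TR window holds 15 samples |
| `boundary_attraction` | – (0–1) | 0 | wall-ward path bending |
| `lambda` | – (0–1) | 0 | response displacement toward the nearer wall |
| `sigma0` | vm | 2 | baseline response noise SD |
| `sigma1` | vm per vm | 0.02 | noise growth per vm of target two-wall distance |
| `lambda_sd`, `attraction_sd` | – | 0 | between-participant spread |

The sampling rate is not a task constant; 10 Hz was chosen once so that
per-TR windows contain enough samples for stable window means, and is not
revisited.

**Path model.** With `boundary_attraction = 0` the agent rotates toward
the goal and takes the beeline. With attraction `a > 0`, a single
intermediate waypoint is placed part-way along the beeline (uniformly at
35–65% of the way) and displaced toward its nearest wall by a random
fraction `a * U(0.5, 1)` of its wall distance. This is the simplest
mechanism that produces BPI different from 1 while preserving the
straight-segment kinematics; it is a stand-in for whatever shape real
paths have, not a behavioral claim. Because the waypoint is stochastic, a
seed is required whenever attraction is positive.

**Response model.** Spatial recall is modeled in the spirit of category
adjustment: memory blends metric information with coarse categorical
anchors, and boundaries are the dominant anchors in an arena. Per axis,
the response coordinate is the target coordinate displaced toward its
nearer wall by fraction `lambda` of the axis wall distance, then perturbed
by centered Gaussian noise with SD `sigma0 + sigma1 * d`, where `d` is the
target's summed two-wall distance. The linear noise model keeps the
distance-dependence identifiable in recovery tests. Responses falling
outside the arena are clipped to the walls rather than resampled —
resampling would distort the noise distribution near walls — and clipping
events are flagged in the trial table.

**Group defaults.** `default_group_params()` encodes the two study
conditions. The young group is essentially unbiased (`lambda = 0`, mild
attraction 0.10, `sigma0 = 2`, `sigma1 = 0.02`); the old group is pulled
toward walls (`lambda = 0.12`, attraction 0.35, `sigma0 = 3`,
`sigma1 = 0.05`) with larger between-participant spread. These values were
fixed once by Monte-Carlo calibration so that the young cohort's mean
boundary bias lies in [0.95, 1.05], the old cohort's exceeds 1.05, and
mean error rises with target boundary distance; the test suite asserts
exactly these signatures.

**Cohorts.** `simulate_cohort()` derives one sub-seed per participant from
the master seed through a deterministic counter scheme
(`derive_seed(master, index)`), so cohorts are reproducible and growing
one group leaves the other group's data byte-identical. Per-participant
parameter values are drawn around the group values (truncated to the legal
range), giving the between-participant variance that the correlational
analyses need. Per-run trial counts default to 48 (young) and 37 (old),
mirroring the groups' different trial throughput at matched scan time.

## Behavioral metrics

* **Feedback classes**: green for error in [0, 20) vm, yellow for
  [20, 30], red above 30; re-encoding is triggered strictly above 20 vm.
  Behavior exactly at the thresholds is not dictated by the task
  description; the half-open convention here is centralized in
  `feedback_class()` and configurable.
* **Boundary bias**: target wall distance over response wall distance,
  per axis, averaged (two-wall variant), or as a single nearest-wall
  ratio.
* **BPI**: both paths are reduced to translation samples; the beeline is
  resampled at the trajectory's own rate and speed, so both paths receive
  the same per-sample treatment. The central tendency is the median by
  default, with a mean variant; the two correlate almost perfectly on
  simulated cohorts, and the test suite asserts r > 0.9.
* **Outlier filter**: per participant, trials whose error lies more than
  1.5 × IQR below Q1 or above Q3 of that participant's own error
  distribution are removed. Quantiles use linear interpolation (type 7) —
  stated explicitly because quartile conventions change which trials
  survive. With fewer than 4 trials the filter is skipped with a warning.
* **Aggregation**: bias and BPI aggregate to participants as the mean of
  per-trial values; the summary table also carries medians, and both
  trial-level and participant-level tables are available downstream, since
  the aggregation level is an open choice.

## The first-level fMRI model

`scan_config()` fixes TR = 1.5 s, run duration 960 s (640 volumes), a
128-s high-pass cutoff, and 5 aCompCor components.

* **Events.** TR windows are half-open, `[k·tr, (k+1)·tr)`; boundary
  samples belong to the later TR. A TR is a translation event if *any*
  translation sample falls inside it; the translated fraction of each
  window is recorded so stricter (e.g. majority) rules can be evaluated.
  Each event has fixed duration one TR.
* **Modulator.** Per event, the mean per-axis nearer-wall distance is
  computed across *all* samples of the full window — movement within a
  window is continuous, so restricting to moving samples would only add
  sampling noise — and summed over x and y. Values are mean-centered over
  the run's events (standard modulator convention, guaranteeing
  condition/modulator separability; a constant modulator is reported as
  inestimable) and entered as a first-order term without
  orthogonalization.
* **HRF.** Canonical double-gamma (response peak 6 s, undershoot 16 s,
  ratio 6, length 32 s), unit peak, sampled at TR; convolution is linear
  and causal.
* **Drift.** An orthonormal DCT basis with `floor(2·T/cutoff)` columns
  (15 at the defaults) joins the design, which is equivalent to high-pass
  filtering both sides of the model; this one convention is used
  throughout.
* **Nuisance.** Six motion parameters and the leading principal
  components of the voxel-demeaned noise-mask series (aCompCor), unit-norm
  and mutually orthogonal, enter unconvolved.
* **Estimation.** OLS without autocorrelation prewhitening. This is a
  deliberate, documented simplification: simulated noise retains AR(1)
  structure, so recovery tests are honest about it, and the group-level
  one-sample test across runs stays calibrated because between-run
  variability is estimated empirically (the null-calibration experiment
  verifies ~5% rejections).
* **Quality metrics.** tSNR = temporal mean / temporal SD. Motion
  summaries are the framewise absolute differences summed over the three
  translations (and separately the three rotations), averaged over the
  run. "Displacement per volume" could also be read as summed parameter
  magnitudes; the framewise-difference reading was chosen as the standard
  motion-summary convention and is stated here because the two differ.
* **Truncation control.** `truncate_run()` removes the final
  `floor(fraction · n)` volumes and any events inside them (default use
  case: shortening one group's runs by 19.84% to match the other), after
  which the design is rebuilt.

## The BOLD generator

`simulate_bold_run()` is the generative twin of that first-level model:
signal = convolved condition × `beta_condition` + convolved centered
modulator × `beta_pmod` + motion leakage + physiological signals + drift +
AR(1) noise, on a baseline of 100 (tSNR scale). Two band-limited
physiological sources are shared between the ROI and a bank of synthetic
noise-mask voxels, so aCompCor can be exercised on the same run it
protects; drift is built inside the DCT span so the noiseless model is
exactly identified, which makes "noiseless recovery is exact" a meaningful
test rather than an approximation. The generating truth is returned with
every run. The default effect scale (`beta_pmod = -0.004` signal units
per vm) and noise (`ar1_phi = 0.3`, marginal SD 1) were fixed once; at
this signal-to-noise level 200-run recovery experiments return the
generating value within a few percent with the correct sign in every run,
and the test suite requires ±20% and ≥95% sign agreement.

The null-calibration experiment (`pmod_null_calibration()`) keeps a fixed
pool of sessions/designs and redraws only the AR(1) noise per replication.
This is exact, not a shortcut: every deterministic signal component lies
in the design span, so it contributes precisely zero to the modulator
estimate, and only noise propagates into the group test.

## Group-level inference

* One-sample t-tests are two-sided with a Shapiro–Wilk precheck reported
  alongside (warning at p ≤ 0.05).
* The Bayesian one-sample test uses the conventional default prior: a
  zero-centered Cauchy with scale √2/2 on the standardized effect,
  integrated numerically against the noncentral-t likelihood. The test
  suite cross-checks it against an independent implementation through the
  g-prior mixture representation to 1e-4 and tighter.
* Levene's test is the classic mean-centered variant (deviation ANOVA),
  matching its name; the median-centered variant is not what is computed.
* The median split of older adults by mean Euclidean error sends
  participants at or below the median — including the odd middle
  participant — to the low-error (high-performing) subgroup; the rule is
  explicit because with an odd group size some rule must be chosen.
  Subgroup comparisons use pooled-variance t-tests.
* Mixed models (via `lmerTest`) use sum contrasts for age group and
  successive-difference contrasts for target (trash bin→plant,
  plant→ball), with a by-participant random intercept and target slope;
  singular fits fall back to intercept-only and are flagged. Estimation is
  deliberately delegated: this stage is orchestration, not novel
  computation.
* Covariates enter regressions raw (unstandardized); no multiple-testing
  correction is applied by default, matching the reporting style the
  battery mirrors.

## What the simulations do and do not show

The generator reproduces the features the analysis depends on: exact task
kinematics, distance-graded response noise, wall-ward response bias and
path attraction, trial/participant hierarchy, and BOLD runs whose
modulator effect, nuisance structure and autocorrelation are known. It
does not model perception, visibility or view-based strategies, learning
across trials, reaction-time dynamics, or spatially realistic fMRI volumes
(the "image" is a voxel bank sufficient for aCompCor). A path-similarity
measure for view-based navigation is out of scope because no defining
formula was available to implement faithfully. Passing recovery tests
therefore demonstrates that the estimators are correct and calibrated
under the stated generative assumptions — not that real data satisfy those
assumptions.

## Problem sizes and numerical settings used by the tests

The packaged experiments use 200 recovery runs at the default effect and
500 null replications over a 15-participant design pool; cohort-level
checks use 20 young + 21 old participants at the default per-run trial
counts. Brute-force oracle comparisons run on 50 randomly chosen fixture
trials and small statistical toys at tolerance 1e-8 (1e-4 for the Bayes
factor against its independent oracle). Quadrature tolerances are 1e-10
with a single documented relaxation step to 1e-8 if roundoff is reported;
integration failure is always an error, never a silent fallback.
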
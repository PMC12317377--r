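---
title: "Decoding sound categories from multivoxel patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sound categories from multivoxel patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundmvpa)
```

`soundmvpa` reimplements, as a tested pipeline, a multivoxel pattern
analysis (MVPA) of fMRI responses to natural sounds organized in a
three-tier semantic taxonomy: 2 superordinate categories (animate,
inanimate), 4 intermediate categories (humans, animals, vehicles,
objects), 12 subordinate categories, and 36 individual sound exemplars.
This vignette documents the statistical models, the tunable parameters and
their defaults, the synthetic-data generator the test suite relies on, and
the design choices made where the design was genuinely open.

## Experimental design

The design encoded by `generate_schedule()` presents each of the 36
exemplars 12 times (432 sound trials) over 4 functional runs, each
exemplar appearing exactly 3 times per run. Sounds last 2–3 s (a fixed
per-exemplar duration drawn uniformly), separated by a 4 s
inter-stimulus interval jittered in ±0.5 s steps. 10% of sound trials
carry a target beep (half 800 Hz, half 400 Hz) for an attention task, and
an additional 10% of the sound-trial count are silent null events.

Three choices were open and are fixed as follows:

* **Pseudo-randomization** means, here, a uniform shuffle subject to "no
  immediate repetition of the same exemplar" — the weakest constraint
  consistent with the term.
* **The null-event base** is 10% of the 432 sound trials (43 events),
  spread as evenly as possible across runs.
* **Beep placement** is uniform over sound trials; only the rate and the
  two pitches are prescribed by the design.

## Signal model of the synthetic generator

`simulate_event_patterns()` generates, per participant, a fixed unit-norm
random "prototype" pattern for every category label at every tier. A
sound trial's voxel vector is

$$\beta_{t} \;=\; \sum_{\ell \in \text{tiers}} a_\ell \,
p^{(\ell)}_{c_\ell(t)} \;+\; r_{\text{run}(t)} \;+\; \varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0, \sigma^2 I),$$

with tier amplitudes $a_\ell$ (default 0), a per-run offset pattern
$r$ (SD 0.2) emulating slow session drifts, and unit noise SD. Prototypes
are spherically symmetric and mean-free, so category information lives in
the *spatial pattern*, not in the regional mean — matching the analysis
logic in which univariate region-of-interest statistics show no
category differences while the classifier succeeds. With all amplitudes
zero the generator is label-exchangeable, the property the permutation
calibration tests exploit.

What the generator does *not* emulate: physiological noise spectra,
spatial autocorrelation of real BOLD data, vascular artifacts,
inter-regional structure, or surface (vertex) geometry. Passing tests
therefore validate the *statistical machinery* — estimators, resampling,
error control — not the biological claim; real-data effect sizes cannot
be reproduced at desk scale.

Defaults mirror the study conditions: 18 participants, 4 runs,
ROI-sized voxel sets (80 voxels). For cohorts carrying signal,
`default_synthetic_config()` plants superordinate and intermediate
amplitude 0.28. That value was calibrated once, by Monte-Carlo over 60
replicate cohorts at the default geometry, to give a group effect size
(Cohen's d against chance) near 0.6 for the two-category decoding —
0.6 being the prior effect size the design's power analysis assumed
(see below). The calibration was frozen before the detection-rate checks
were run and is not revisited.

## Event-wise betas

`build_design()` places one regressor per sound event — its boxcar
convolved with a canonical double-gamma hemodynamic response (peak ≈ 5 s,
undershoot ≈ 15 s), computed on a 16× oversampled grid and sampled at
TR = 2 s — plus an intercept and optional orthogonal-polynomial drift
columns. `estimate_betas()` solves the single least-squares-all model by
QR decomposition and returns the event betas. A one-GLM-per-event variant
was not implemented: events are well separated (≈ 6.5 s
onset-to-onset), where the single-model estimator is standard and
unbiased, and the generating software of the original betas is not
specified in any case. High-pass filtering is preprocessing and out of
scope; the drift columns (default order 0 in the estimator, 2 where
used) stand in for it on synthetic data.

## The decoding pipeline

For each participant: (1) `zscore_events()` standardizes each voxel's
betas to mean 0, SD 1 across all events; (2) `average_conditions()`
averages events into one pattern per run × decoded category; (3) per
cross-validation fold, the training patterns are min–max scaled voxel-wise
to [−1, 1] and the same affine map is applied to the held-out run
(`scale_train_apply_test()`; test values are *not* clipped); (4)
`loro_cv_decode()` trains a linear soft-margin support-vector classifier
(C = 1, the LIBSVM default the original toolbox uses) on 3 runs and tests
on the remaining one, cycling over the 4 runs.

The source analysis describes both a "z-transform" of the betas and
scaling of the training data "to lie between −1 and 1"; steps (1) and
(3) implement the two statements as successive stages — event-level
standardization, then the fold-wise min–max scaling that the classifier
library's workflow prescribes. Multiclass problems use one-vs-one with
majority vote; vote ties resolve deterministically to the alphabetically
first class. With one test pattern per condition per fold, an
n-condition task yields mean accuracies on the exact grid of multiples
of 1/(4n) — 0.125 steps for the two-category task — which the tests
assert.

The classifier itself is a compact SMO solver for the C-SVC dual
(maximal-violating-pair selection, stopping tolerance 10⁻³, bias from the
free support vectors), written in C++ so that the permutation analyses
below stay inside desk-scale budgets; its predictions are cross-checked
against the LIBSVM reference implementation (`e1071`) in the test suite,
where agreement is exact away from the decision boundary.

## Group inference

Statistical significance is assessed by permutation.
`participant_null()` rebuilds, per iteration, the entire pipeline under
randomized trial labels: event labels are permuted *within runs*, the
patterns re-averaged, fold scaling re-fit, and the full leave-one-run-out
classification re-run. The group null is the per-iteration average of the
18 participants' null accuracies (iterations aligned), and the group
p-value is the add-one permutation rule
$(\#\{\text{null} \ge \text{observed}\} + 1)/(n_{\text{perm}} + 1)$; the
plain counting probability is reported alongside (`p_literal`). Effect
sizes are Cohen's d against the theoretical chance level, with the
sample (n − 1) SD.

One design point deserves emphasis. Permuting the labels of the
*already-averaged* run × condition patterns — superficially the simpler
scheme — produces class-imbalanced training folds whose majority class
anti-correlates with the held-out composition; on signal-free data that
null centers near 0.39 rather than 0.5, and a test against it is
anti-conservative. The event-level within-run scheme preserves per-run
class counts, keeps the null centered at chance (the study likewise
reports its empirical chance indistinguishable from the theoretical
level), and is the package default. The biased variant remains available
(`scheme = "patterns"`) and its miscalibration is itself asserted in the
tests as documentation.

The permutation count defaults to 1,000; calibration simulations in the
tests and the acceptance script use 200 permutations and 200 replicate
experiments, the reduced counts at which the binomial error of the
estimates is still well below the margins being checked. These problem
sizes (18 participants, 80 voxels, 200 × 200) are the package's chosen
desk-scale operating point.

## Searchlight mapping

`searchlight_decode()` runs the identical pipeline on every sphere of
radius 3 voxels (123 voxel offsets; Euclidean norm, center included,
clipped at the mask). Because z-scoring, averaging and min–max scaling
are all voxel-wise, they commute with voxel subsetting, and a sphere
covering exactly a region's voxel set reproduces the region pipeline's
accuracy bit for bit — an equivalence the tests assert. Group maps use a
one-sided one-sample t against chance per voxel.

Cluster-size correction is Monte-Carlo: `cluster_threshold()` simulates
smoothness-matched Gaussian noise volumes, thresholds them at the
voxelwise level (default p < 0.01), records the maximum 26-connected
cluster size per volume, and takes the 95th percentile as the minimum
surviving size. The original correction tool's internals (iterations,
connectivity) are not published; 26-connectivity and Gaussian-FWHM
smoothness matching are the documented stand-ins here.

## Acoustic stimulus controls

The stimulus-control module mirrors the acoustic analyses: Welch power
spectral density (Hann window, 1024-sample segments, 50% overlap,
one-sided density normalized to conserve power); harmonics-to-noise ratio
by the windowed-autocorrelation method (40 ms Hann frames, 10 ms hop,
minimum fundamental 75 Hz, window-autocorrelation correction,
HNR = 10·log₁₀(r/(1−r))); the amplitude envelope as the smoothed analytic
signal magnitude, peak-normalized; and attack as the relative time of the
first local envelope maximum with height ≥ 0.5. Two numerical guards are
worth noting: the envelope's moving average uses edge-renormalized
windows, and a candidate attack peak must dominate its ±50 ms
neighborhood, which prevents micro-wiggles of a noisy envelope at the
0.5 crossing from masquerading as the first peak. Per-category
comparisons use the classical one-way ANOVA (4 categories × 9 sounds:
df = 3, 32) with Benjamini–Hochberg-corrected post-hoc t-tests. The
original sounds' specific significant frequency bands are not
reproducible without the actual recordings; `synth_audio()` provides
harmonic, noise and amplitude-modulated fixtures with known ground truth
instead.

## Power utilities

`power_one_sample_t()` evaluates the exact noncentral-t power of the
one-sample t-test; `min_n_for_power()` inverts it. The design's power
analysis is reconstructed as a *one-tailed* test (decoding must exceed
chance, matching the one-sided top-5% permutation rule):

```{r power}
min_n_for_power(d = 0.6, alpha = 0.05, tail = "one", target_power = 0.80)
round(100 * power_one_sample_t(d = 0.6, n = 18, alpha = 0.05, tail = "one"))
```

The noncentral-t form (not the normal approximation) is required to
resolve 79% from 78% at these sample sizes.

## A worked example

A small cohort, end to end (the defaults run 18 participants and 1,000
permutations; this example is scaled down to keep the vignette quick):

```{r example}
cfg <- pipeline_config(
  synthetic = default_synthetic_config(seed = 42, n_participants = 8,
                                       n_voxels = 40),
  tasks = c("superordinate", "intermediate"),
  n_perm = 200, seed = 42)
report <- run_experiment(cfg)
report$report[, c("task", "chance", "observed", "p", "d", "significant")]
```

## Known limitations

* Synthetic cohorts validate machinery, not neuroscience: spatial noise
  structure, preprocessing artifacts and real ROI geometry are absent.
* The event-level GLM variant, the permutation granularity and the
  cluster-correction null model of the original analysis chain are not
  fully specified by its description; the choices here are documented
  reconstructions, not claims about the original implementation.
* Repeated-measures ANOVAs and post-hoc machinery on pooled pairwise
  accuracies are consumed from standard tools; this package only emits
  the tidy per-participant tables they need (`pool_human_nonhuman()`).
* Surface-based (vertex) analyses and anatomical labeling of searchlight
  clusters are out of scope.
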
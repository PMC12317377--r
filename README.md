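# soundmvpa

Multivoxel pattern decoding of natural sound categories from fMRI
responses — a tested, reusable reimplementation of a full
sound-category decoding analysis, driven by a synthetic-data generator so
that every stage is verifiable without any data download.

## The problem

Auditory information reaches early visual cortex as feedback, and the
category of a heard sound (animate vs. inanimate; human, animal, vehicle
or object) can be decoded from the spatial pattern of fMRI responses
there even though the mean regional activation shows no category
differences. Analyses of this kind chain together many statistical steps
— event-wise beta estimation, pattern standardization, leave-one-run-out
support-vector classification, group permutation inference, searchlight
mapping, acoustic stimulus controls — and each step has calibration
properties that can silently break. `soundmvpa` implements the whole
chain as composable, tibble-in/tibble-out R functions, and ships the
property tests that demonstrate each step behaves as advertised. It is
aimed at researchers reproducing or extending category-decoding analyses
and at methodologists studying the calibration of decoding pipelines.

## The analysis in brief

A cohort listens to 36 natural sounds (3 exemplars × 12 subcategories,
nested in 4 categories and an animate/inanimate division), each presented
12 times across 4 runs (432 trials, 10% carrying target beeps, plus 10%
null events, ISI 4 ± 0.5 s). Per participant and region, one beta per
sound event and voxel is estimated by OLS from the
hemodynamic-response-convolved design; betas are z-scored voxel-wise,
averaged into one pattern per run × category, min–max scaled to [−1, 1]
per cross-validation fold, and classified with a linear soft-margin SVM
(C = 1), training on 3 runs and testing on the held-out run. With one
test pattern per category per fold, an n-category task yields mean
accuracies on the exact 1/(4n) grid (0.125 steps for 2 categories).
Group significance comes from a permutation test: trial labels are
randomized within runs, the entire pipeline re-run (1,000 iterations),
and the group p-value is the add-one rank of the observed group mean in
the permuted group means,
`p = (#{null ≥ observed} + 1) / (n_perm + 1)`,
with Cohen's `d = (mean − chance) / sd` as effect size. A searchlight
(radius 3 voxels, 123 offsets) maps the same pipeline across a volume
with Monte-Carlo cluster-size correction, and acoustic controls (Welch
PSD, harmonics-to-noise ratio `10·log10(r/(1−r))`, amplitude envelope,
attack) check that category distinctions are not trivially acoustic.

## A worked example

```r
library(soundmvpa)

cfg <- pipeline_config(
  synthetic = default_synthetic_config(seed = 42, n_participants = 8,
                                       n_voxels = 40),
  tasks = c("superordinate", "intermediate"),
  n_perm = 200, seed = 42)
report <- run_experiment(cfg)
report$report[, c("task", "chance", "observed", "p", "d", "significant")]
#> # A tibble: 2 × 6
#>   task          chance observed       p     d significant
#>   <chr>          <dbl>    <dbl>   <dbl> <dbl> <lgl>
#> 1 superordinate   0.5     0.75  0.00498 1.41  TRUE
#> 2 intermediate    0.25    0.328 0.0299  0.589 TRUE
```

The synthetic cohort plants a distributed category signal whose amplitude
(0.28) is calibrated to a group effect size near 0.6 — the prior effect
size the design's power analysis assumed. Here the two-category decoding
reaches 75% (chance 50%) with permutation `p ≈ 0.005` and `d ≈ 1.4`,
and the four-category decoding 32.8% (chance 25%); with only 8
participants the run-to-run variability of such estimates is substantial,
which is exactly what the power utilities quantify:

```r
min_n_for_power(d = 0.6, alpha = 0.05, tail = "one", target_power = 0.80)
#> [1] 19
round(100 * power_one_sample_t(d = 0.6, n = 18, alpha = 0.05, tail = "one"))
#> [1] 79
```

Each piece is also usable on its own: `build_taxonomy()` /
`generate_schedule()` for the design, `simulate_event_patterns()` /
`simulate_timeseries()` for synthetic data, `build_design()` /
`estimate_betas()` for the GLM, `zscore_events()` |>
`average_conditions()` |> `loro_cv_decode()` for decoding,
`participant_null()` / `group_test()` for inference,
`searchlight_decode()` / `cluster_threshold()` for mapping, and
`psd_welch()` / `hnr()` / `sound_envelope()` / `attack_time()` for
acoustics. Results have `tidy()`, `glance()` and `autoplot()` methods.

See `vignettes/decoding-sound-categories.Rmd` for the models,
parameter choices and known limitations.

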
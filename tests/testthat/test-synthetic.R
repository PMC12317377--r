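test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_voxels = 1), "n_voxels")
  expect_error(synthetic_config(tier_amplitudes = c(superordinate = -1)),
               ">= 0")
  expect_error(synthetic_config(tier_amplitudes = c(banana = 1)),
               "unknown tier")
})

test_that("event-pattern generator is seed-reproducible and aligned with the schedule", {
  fx <- fixture_cohort(n_participants = 2, seed = 5, zscore = FALSE)
  fx2 <- fixture_cohort(n_participants = 2, seed = 5, zscore = FALSE)
  expect_identical(fx$data, fx2$data)
  snd <- fx$schedule[fx$schedule$kind == "sound", ]
  one <- fx$data[fx$data$participant == 1, ]
  expect_equal(nrow(one), nrow(snd))
  expect_equal(one$exemplar, snd$exemplar)
  expect_true(all(is.finite(fx$data$beta)))
})

test_that("planted superordinate signal separates classes; zero signal stays at chance", {
  sched <- generate_schedule(fixture_tree(), n_runs = 4, reps_per_sound = 4,
                             beep_frac = 0, null_frac = 0, seed = 11)
  task <- classification_task("superordinate")
  # amplitude >> noise: perfect decoding
  strong <- fixture_cohort(n_participants = 2, n_voxels = 30,
                           amplitudes = c(superordinate = 50),
                           seed = 3, schedule = sched)
  acc_strong <- decode_participants(strong$data, task)$accuracy
  expect_equal(acc_strong, c(1, 1))
  # no signal: group accuracy near chance over replicate cohorts
  accs <- vapply(1:15, function(s) {
    fx <- fixture_cohort(n_participants = 3, n_voxels = 30, seed = 20 + s,
                         schedule = sched)
    mean(decode_participants(fx$data, task)$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5),
            3 * stats::sd(accs) / sqrt(length(accs)) + 0.01)
})

test_that("doubling the noise cannot raise expected decoding accuracy", {
  sched <- generate_schedule(fixture_tree(), n_runs = 4, reps_per_sound = 4,
                             beep_frac = 0, null_frac = 0, seed = 12)
  task <- classification_task("superordinate")
  tree <- fixture_tree()
  mean_acc <- function(noise_sd, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- synthetic_config(n_participants = 2, n_voxels = 30,
                              tier_amplitudes = c(superordinate = 0.8),
                              noise_sd = noise_sd, seed = s)
      dat <- zscore_events(simulate_event_patterns(cfg, sched, tree))
      mean(decode_participants(dat, task)$accuracy)
    }, numeric(1)))
  }
  seeds <- 101:124
  expect_gt(mean_acc(1, seeds), mean_acc(2, seeds))
})

test_that("synthetic audio has the advertised spectral and envelope structure", {
  w <- synth_audio("harmonic", f0 = 440, duration_s = 2, seed = 1)
  expect_lte(max(abs(w$samples)), 1)
  p <- psd_welch(w)
  df <- p$frequency[2] - p$frequency[1]
  expect_lt(abs(p$frequency[which.max(p$power)] - 440), df)
  am <- synth_audio("am_noise", attack_frac = 0.25, seed = 2)
  env <- sound_envelope(am, smooth_ms = 50)
  expect_equal(max(env$amplitude), 1)
  expect_lt(abs(attack_time(env, am$duration_s) - 0.25), 0.05)
  expect_error(synth_audio("harmonic", f0 = 30000, sample_rate = 44100),
               "aliasing")
})

test_that("noiseless time series reproduce the event regressors and betas", {
  tree <- fixture_tree()
  sched <- generate_schedule(tree, n_runs = 2, reps_per_sound = 2,
                             beep_frac = 0, null_frac = 0, seed = 3)
  cfg <- synthetic_config(n_participants = 1, n_voxels = 4, seed = 4)
  dat <- simulate_event_patterns(cfg, sched, tree)
  ts <- simulate_timeseries(dat, sched, ar1_coeff = 0, noise_sd = 1e-10,
                            seed = 5)
  est <- estimate_betas_dataset(ts, sched, tree)
  expect_equal(est$beta, dat$beta, tolerance = 1e-6)
  expect_error(simulate_timeseries(dat, sched, ar1_coeff = 1.2),
               "ar1_coeff")
})

test_that("AR(1) noise leaves beta recovery unbiased", {
  tree <- fixture_tree()
  sched <- generate_schedule(tree, n_runs = 1, reps_per_sound = 1,
                             beep_frac = 0, null_frac = 0, seed = 6)
  cfg <- synthetic_config(n_participants = 1, n_voxels = 30, seed = 7)
  dat <- simulate_event_patterns(cfg, sched, tree)
  errs <- vapply(1:20, function(s) {
    ts <- simulate_timeseries(dat, sched, ar1_coeff = 0.3, noise_sd = 1,
                              seed = 100 + s)
    est <- estimate_betas_dataset(ts, sched, tree)
    mean(est$beta - dat$beta)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 2 * stats::sd(errs) / sqrt(length(errs)) + 0.02)
})
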
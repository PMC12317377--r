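# Shared fixtures, built in code. The full design (4 runs x 36 exemplars x
# 3 reps) is cheap to generate; smaller designs are used where the test
# only needs structure.

fixture_tree <- function() build_taxonomy()

fixture_schedule <- function(seed = 1L, ...) {
  generate_schedule(fixture_tree(), seed = seed, ...)
}

# A small cohort of z-scored event patterns.
fixture_cohort <- function(n_participants = 3, n_voxels = 20,
                           amplitudes = c(superordinate = 0),
                           seed = 1L, schedule = NULL, zscore = TRUE) {
  tree <- fixture_tree()
  sched <- if (is.null(schedule)) fixture_schedule(seed = seed) else schedule
  cfg <- synthetic_config(n_participants = n_participants,
                          n_voxels = n_voxels,
                          tier_amplitudes = amplitudes, seed = seed)
  dat <- simulate_event_patterns(cfg, sched, tree)
  if (zscore) dat <- suppressWarnings(zscore_events(dat))
  list(tree = tree, schedule = sched, data = dat)
}

# Hand-built condition patterns for one participant: `centers` is a named
# list condition -> voxel vector; per-run patterns are center + noise.
fixture_patterns <- function(centers, n_runs = 4, noise_sd = 0.1,
                             seed = 1L) {
  set.seed(seed)
  conds <- names(centers)
  nv <- length(centers[[1]])
  rows <- expand.grid(run = seq_len(n_runs), condition = conds,
                      stringsAsFactors = FALSE)
  out <- tibble::as_tibble(rows)
  out$pattern <- do.call(rbind, lapply(seq_len(nrow(out)), function(i)
    centers[[out$condition[i]]] + rnorm(nv, sd = noise_sd)))
  out
}
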
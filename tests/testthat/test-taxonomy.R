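test_that("taxonomy has the full three-tier structure", {
  tree <- build_taxonomy()
  expect_equal(nrow(tree), 36)
  expect_equal(length(unique(tree$subordinate)), 12)
  expect_setequal(unique(tree$intermediate),
                  c("humans", "animals", "vehicles", "objects"))
  expect_setequal(unique(tree$superordinate), c("animate", "inanimate"))
  # regular branching: 3 exemplars per subordinate, 3 subordinates per
  # intermediate, 2 intermediates per superordinate
  expect_true(all(table(tree$subordinate) == 3))
  sub_per_int <- tapply(tree$subordinate, tree$intermediate,
                        function(x) length(unique(x)))
  expect_true(all(sub_per_int == 3))
  int_per_sup <- tapply(tree$intermediate, tree$superordinate,
                        function(x) length(unique(x)))
  expect_true(all(int_per_sup == 2))
  # every exemplar has exactly one label per tier
  expect_false(anyDuplicated(tree$exemplar) > 0)
  duck <- tree[tree$exemplar == "duck", ]
  expect_equal(duck$subordinate, "birds")
  expect_equal(duck$intermediate, "animals")
  expect_equal(duck$superordinate, "animate")
})

test_that("generated schedule satisfies the design arithmetic", {
  tree <- fixture_tree()
  sched <- generate_schedule(tree, seed = 1)
  snd <- sched[sched$kind == "sound", ]
  expect_equal(nrow(snd), 432)
  expect_true(all(table(snd$exemplar) == 12))
  expect_equal(as.vector(table(snd$run)), rep(108, 4))
  expect_equal(sum(sched$beep != "none"), round(0.10 * 432))
  expect_equal(sum(sched$kind == "null"), round(0.10 * 432))
  expect_true(all(sched$isi_s %in% c(3.5, 4.0, 4.5)))
  expect_true(all(snd$duration_s >= 2 & snd$duration_s <= 3))
  # onsets strictly increasing within each run
  for (r in 1:4) {
    on <- sched$onset_s[sched$run == r]
    expect_true(all(diff(on) > 0))
  }
  # beeps only on sound trials, split between the two pitches
  expect_true(all(sched$kind[sched$beep != "none"] == "sound"))
  expect_equal(sum(sched$beep == "high_800Hz"), 22)
  expect_equal(sum(sched$beep == "low_400Hz"), 21)
})

test_that("pseudo-randomization forbids immediate exemplar repeats and is seed-reproducible", {
  tree <- fixture_tree()
  s1 <- generate_schedule(tree, seed = 7)
  s2 <- generate_schedule(tree, seed = 7)
  s3 <- generate_schedule(tree, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  for (r in 1:4) {
    ex <- s1$exemplar[s1$run == r & s1$kind == "sound"]
    expect_false(any(ex[-1] == ex[-length(ex)]))
  }
})

test_that("degenerate and indivisible designs are handled", {
  tree <- fixture_tree()
  s <- generate_schedule(tree, n_runs = 1, reps_per_sound = 1,
                         beep_frac = 0, null_frac = 0, isi_jitter_s = 0,
                         seed = 0)
  expect_equal(nrow(s), 36)
  expect_true(all(s$kind == "sound"))
  expect_true(all(s$beep == "none"))
  expect_error(generate_schedule(tree, n_runs = 5, seed = 1),
               "divisible")
})

test_that("labels_for_level maps trials to balanced tier labels", {
  tree <- fixture_tree()
  sched <- fixture_schedule(seed = 2)
  sup <- labels_for_level(sched, tree, "superordinate")
  expect_equal(as.vector(table(sup)), c(216, 216))
  int <- labels_for_level(sched, tree, "intermediate")
  expect_true(all(table(int) == 108))
  ex <- labels_for_level(sched, tree, "exemplar")
  expect_equal(length(unique(ex)), 36)
  # null trials excluded
  expect_equal(length(sup), sum(sched$kind == "sound"))
  # empty schedule -> empty vector
  empty <- sched[0, ]
  expect_identical(labels_for_level(empty, tree, "subordinate"),
                   character(0))
  # unknown exemplar -> error
  bad <- sched
  bad$exemplar[bad$kind == "sound"][1] <- "theremin"
  expect_error(labels_for_level(bad, tree, "superordinate"), "absent")
})

test_that("schedules and the taxonomy round-trip through CSV", {
  sched <- fixture_schedule(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sched, path)
  back <- read_schedule_csv(path)
  expect_equal(back$exemplar, sched$exemplar)
  expect_equal(back$onset_s, sched$onset_s, tolerance = 1e-12)
  tree <- build_taxonomy()
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_taxonomy_csv(tree, tpath)
  expect_equal(read_taxonomy_csv(tpath), tree)
  shipped <- read_taxonomy_csv(system.file("extdata", "sound_taxonomy.csv",
                                           package = "soundmvpa"))
  expect_equal(shipped, tree)
})
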
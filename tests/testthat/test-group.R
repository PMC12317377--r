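test_that("group permutation p-values follow the counting rules", {
  set.seed(1)
  nulls <- matrix(runif(5 * 1000, 0.3, 0.7), 5, 1000)
  # observed above every null group mean: add-one p = 1/1001
  gt <- group_test(c(0.88, 0.9, 0.92, 0.9, 0.9), nulls, chance = 0.5)
  expect_equal(gt$p_value, 1 / 1001)
  expect_equal(gt$p_literal, 0)
  expect_true(gt$significant)
  # observed at the bottom: p ~ 1
  gt2 <- group_test(c(0.1, 0.12, 0.08, 0.1, 0.1), nulls, chance = 0.5)
  expect_equal(gt2$p_value, 1)
  expect_equal(gt2$p_literal, 1)
  # direct-count oracle for an interior value
  obs <- c(0.5, 0.52, 0.54, 0.52, 0.52)
  gt3 <- group_test(obs, nulls, chance = 0.5)
  k <- sum(colMeans(nulls) >= mean(obs))
  expect_equal(gt3$p_value, (k + 1) / 1001)
  expect_equal(gt3$p_literal, k / 1000)
  expect_error(group_test(rep(0.5, 4), nulls), "participants must match")
})

test_that("Cohen's d matches its arithmetic definition", {
  expect_equal(cohens_d(c(0.5, 0.625, 0.75), 0.5), 1)
  expect_equal(cohens_d(c(0.4, 0.5, 0.6), 0.5), 0)  # centered on chance
  expect_warning(d0 <- cohens_d(c(0.6, 0.6), 0.5), "zero variance")
  expect_true(is.na(d0))
  expect_error(cohens_d(0.7, 0.5), ">= 2")
})

test_that("permutation null centers at chance and is reproducible", {
  fx <- fixture_cohort(n_participants = 2, n_voxels = 20, seed = 31)
  task <- classification_task("superordinate")
  one <- fx$data[fx$data$participant == 1, ]
  n1 <- participant_null(one, task, n_perm = 150, seed = 8)
  n2 <- participant_null(one, task, n_perm = 150, seed = 8)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_length(participant_null(one, task, n_perm = 1, seed = 1), 1)
  # strongly separable data still yield a chance-level null
  sep <- fixture_cohort(n_participants = 1, n_voxels = 20,
                        amplitudes = c(superordinate = 50), seed = 32)
  obs <- decode_participants(sep$data, task)$accuracy
  expect_equal(obs, 1)
  nl <- participant_null(sep$data, task, n_perm = 300, seed = 9)
  expect_lt(abs(mean(nl) - 0.5), 3 * stats::sd(nl) / sqrt(300))
})

test_that("pattern-label permutation scheme is retained but biased below chance", {
  fx <- fixture_cohort(n_participants = 1, n_voxels = 20, seed = 33)
  task <- classification_task("superordinate")
  patt <- average_conditions(fx$data, task)
  nl <- participant_null(patt, task, n_perm = 400, seed = 10,
                         scheme = "patterns")
  # the documented miscalibration: mean visibly below 0.5
  expect_lt(mean(nl), 0.48)
})

test_that("human and nonhuman pairwise accuracies pool by pair membership", {
  pairs <- c("animals-humans", "humans-objects", "humans-vehicles",
             "animals-objects", "animals-vehicles", "objects-vehicles")
  tbl <- tidyr::expand_grid(participant = 1:2, pair = pairs)
  tbl$accuracy <- c(0.5, 0.625, 0.75, 0.4, 0.5, 0.6,
                    rep(0.7, 6))
  out <- pool_human_nonhuman(tbl)
  expect_equal(out$human_pairs[out$participant == 1], 0.625)
  expect_equal(out$nonhuman_pairs[out$participant == 1], 0.5)
  expect_equal(out$human_pairs[out$participant == 2], 0.7)
  expect_equal(out$nonhuman_pairs[out$participant == 2], 0.7)
  expect_error(pool_human_nonhuman(tbl[-1, ]), "all 6")
})

test_that("univariate ROI statistics flag planted activation but not mean-free patterns", {
  fx <- fixture_cohort(n_participants = 8, n_voxels = 15,
                       amplitudes = c(superordinate = 0.3), seed = 34,
                       zscore = FALSE)
  stats0 <- univariate_roi_stats(fx$data)
  expect_true(all(stats0$p_adj >= stats0$p))
  expect_true(all(stats0$p_adj > 0.05))  # distributed, mean-free patterns
  planted <- fx$data
  planted$beta <- planted$beta + 1
  stats1 <- univariate_roi_stats(planted)
  expect_true(all(stats1$p_adj < 0.01))
  expect_true(all(stats1$t > 0))
})

test_that("imagery correlation reports r(df) per region with FDR across regions", {
  x <- c(1.2, 1.8, 2.4, 3.1, 3.3, 4.0, 4.4, 5.0)
  d <- tibble::tibble(roi = "V3", vviq = x, accuracy = x / 10)
  out <- vviq_correlation(d)
  expect_equal(out$r, 1)
  expect_equal(out$df, 6)
  two <- dplyr::bind_rows(d, tibble::tibble(roi = "V1", vviq = x,
                                            accuracy = rev(x) / 10))
  out2 <- vviq_correlation(two)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$p_adj, pmin(1, stats::p.adjust(out2$p, "BH")))
  const <- tibble::tibble(vviq = rep(3, 5), accuracy = rnorm(5))
  expect_warning(res <- vviq_correlation(const), "constant")
  expect_true(is.na(res$r))
})

test_that("group permutation tidiers summarize the null and verdict", {
  set.seed(2)
  nulls <- matrix(runif(4 * 200, 0.3, 0.7), 4, 200)
  gt <- group_test(c(0.78, 0.8, 0.82, 0.8), nulls, chance = 0.5)
  expect_equal(nrow(tidy(gt)), 200)
  gl <- glance(gt)
  expect_equal(gl$n_perm, 200)
  expect_true(gl$significant)
  expect_s3_class(autoplot(gt), "ggplot")
})
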
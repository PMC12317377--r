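test_that("z-scoring standardizes voxels and is shift-invariant and idempotent", {
  fx <- fixture_cohort(n_participants = 1, n_voxels = 10, zscore = FALSE)
  z <- zscore_events(fx$data)
  expect_lt(max(abs(colMeans(z$beta))), 1e-10)
  expect_equal(apply(z$beta, 2, sd), rep(1, 10), tolerance = 1e-10)
  shifted <- fx$data
  shifted$beta <- shifted$beta + 5
  expect_equal(zscore_events(shifted)$beta, z$beta, tolerance = 1e-10)
  expect_equal(zscore_events(z)$beta, z$beta, tolerance = 1e-10)
  # zero-variance voxel is clamped with a warning
  flat <- fx$data
  flat$beta[, 3] <- 2
  expect_warning(zscore_events(flat), "zero-variance")
})

test_that("condition averaging yields one pattern per run and condition", {
  fx <- fixture_cohort(n_participants = 1, n_voxels = 8)
  task2 <- classification_task("superordinate")
  patt <- average_conditions(fx$data, task2)
  expect_equal(nrow(patt), 8)  # 2 conditions x 4 runs
  # averaging is exact: constant-signal events average to that signal
  const <- fx$data
  v <- seq_len(8)
  is_anim <- const$superordinate == "animate"
  const$beta[is_anim, ] <- matrix(v, sum(is_anim), 8, byrow = TRUE)
  pa <- average_conditions(const, task2)
  expect_equal(as.vector(pa$pattern[pa$condition == "animate", ][1, ]), v)
  # pair tasks exclude all other categories
  pair <- classification_task(pair = c("humans", "objects"))
  pp <- average_conditions(fx$data, pair)
  expect_setequal(unique(pp$condition), c("humans", "objects"))
  expect_equal(nrow(pp), 8)
  # a missing condition in one run is an error
  broken <- fx$data[!(fx$data$run == 2 &
                        fx$data$superordinate == "animate"), ]
  expect_error(average_conditions(broken, task2), "missing condition")
})

test_that("train min-max scaling maps endpoints to [-1, 1] and extends affinely to test", {
  train <- cbind(c(0, 2, 4), c(1, 1, 3))
  test <- cbind(c(6, -2), c(2, 1))
  sc <- scale_train_apply_test(train, test)
  expect_equal(sc$train[, 1], c(-1, 0, 1))
  expect_equal(sc$test[, 1], c(2, -2))   # out of range allowed, not clipped
  expect_equal(sc$test[, 2], c(0, -1))
  flat <- cbind(c(1, 1, 1))
  expect_warning(out <- scale_train_apply_test(flat, cbind(5)),
                 "constant")
  expect_equal(out$train[, 1], c(0, 0, 0))
})

test_that("decoding is invariant to per-voxel affine transforms of the raw patterns", {
  fx <- fixture_cohort(n_participants = 1, n_voxels = 12,
                       amplitudes = c(superordinate = 0.5), seed = 9,
                       zscore = FALSE)
  task <- classification_task("superordinate")
  base <- loro_cv_decode(average_conditions(fx$data, task), task)
  warped <- fx$data
  set.seed(4)
  a <- runif(12, 0.5, 3); b <- rnorm(12)
  warped$beta <- sweep(sweep(warped$beta, 2, a, "*"), 2, b, "+")
  # z-scoring is part of the pipeline and undoes the affine map exactly
  z1 <- zscore_events(fx$data); z2 <- zscore_events(warped)
  r1 <- loro_cv_decode(average_conditions(z1, task), task)
  r2 <- loro_cv_decode(average_conditions(z2, task), task)
  expect_equal(r1$mean_accuracy, r2$mean_accuracy)
  expect_equal(r1$confusion, r2$confusion)
  expect_s3_class(base, "decoding_result")
})

test_that("leave-one-run-out decoding is quantized, bounded and deterministic", {
  task <- classification_task("superordinate")
  # linearly separable: perfect accuracy
  sep <- fixture_patterns(list(animate = c(5, 0, 0, 0),
                               inanimate = c(-5, 0, 0, 0)), seed = 1)
  res <- loro_cv_decode(sep, task)
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$confusion, res$confusion * diag(2) )
  # random patterns: accuracy always on the 1/8 grid; confusion consistent
  for (s in 1:25) {
    rnd <- fixture_patterns(list(animate = rnorm(6), inanimate = rnorm(6)),
                            noise_sd = 2, seed = 100 + s)
    r <- loro_cv_decode(rnd, task)
    expect_equal(r$mean_accuracy * 8, round(r$mean_accuracy * 8))
    expect_equal(sum(diag(r$confusion)) / sum(r$confusion),
                 r$mean_accuracy)
    expect_equal(rowSums(r$confusion), c(animate = 4, inanimate = 4))
  }
  # determinism
  rnd <- fixture_patterns(list(animate = rnorm(6), inanimate = rnorm(6)),
                          seed = 55)
  expect_identical(loro_cv_decode(rnd, task), loro_cv_decode(rnd, task))
})

test_that("4-run n-condition decoding accuracies live on the 1/(4n) grid", {
  for (n_cond in c(3, 4)) {
    centers <- setNames(lapply(seq_len(n_cond), function(i) rnorm(5)),
                        paste0("c", seq_len(n_cond)))
    for (s in 1:10) {
      patt <- fixture_patterns(centers, noise_sd = 3, seed = 200 + s)
      r <- loro_cv_decode(patt)
      g <- r$mean_accuracy * 4 * n_cond
      expect_equal(g, round(g))
    }
  }
})

test_that("classifier predictions match the reference LIBSVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  agree <- 0; strong <- 0; strong_agree <- 0; tot <- 0
  for (i in 1:120) {
    n <- sample(4:12, 1); p <- sample(2:20, 1)
    y <- sample(rep(1:2, length.out = n))
    X <- matrix(rnorm(n * p), n, p)
    Xt <- matrix(rnorm(5 * p), 5, p)
    mine <- soundmvpa:::svc_train_predict(X, as.integer(y), Xt, 1)
    m <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
    ref <- as.integer(as.character(predict(m, Xt)))
    dv <- attr(predict(m, Xt, decision.values = TRUE), "decision.values")
    agree <- agree + sum(mine == ref); tot <- tot + 5
    conf <- abs(dv) > 0.01  # away from the decision boundary
    strong <- strong + sum(conf)
    strong_agree <- strong_agree + sum((mine == ref)[conf])
  }
  expect_equal(strong_agree, strong)  # exact agreement off the boundary
  expect_gt(agree / tot, 0.99)
})

test_that("pairwise task battery enumerates the 6 category pairs", {
  tasks <- make_pairwise_tasks(fixture_tree())
  expect_length(tasks, 6)
  expect_false(any(vapply(tasks, function(t)
    t$classes[1] == t$classes[2], logical(1))))
  human <- vapply(tasks, function(t) "humans" %in% t$classes, logical(1))
  expect_equal(sum(human), 3)
  expect_true(all(vapply(tasks, function(t) t$chance == 0.5, logical(1))))
})

test_that("tidiers and plots expose the decoding result", {
  sep <- fixture_patterns(list(animate = c(3, 0), inanimate = c(-3, 0)),
                          seed = 1)
  res <- loro_cv_decode(sep, classification_task("superordinate"))
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  gl <- glance(res)
  expect_equal(gl$mean_accuracy, 1)
  expect_s3_class(autoplot(res), "ggplot")
})
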
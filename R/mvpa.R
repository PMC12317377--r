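#' Define a classification task
#'
#' A task names the tier of the taxonomy whose labels are decoded
#' (superordinate: 2 classes, intermediate: 4, subordinate: 12), or a single
#' pair of intermediate categories. Pair tasks exclude all other
#' categories' data entirely.
#'
#' @param level `"superordinate"`, `"intermediate"`, or `"subordinate"`.
#' @param pair Optional character vector of two intermediate category names;
#'   when given, `level` is forced to `"intermediate"` and only these two
#'   categories' trials enter the analysis.
#' @return A list of class `classification_task` with elements `level`,
#'   `classes` (NULL for full-tier tasks), and `chance` (1 / number of
#'   classes).
#' @examples
#' classification_task("superordinate")$chance
#' classification_task(pair = c("humans", "objects"))
#' @export
classification_task <- function(level = c("superordinate", "intermediate",
                                          "subordinate"), pair = NULL) {
  if (!is.null(pair)) {
    pair <- sort(unique(as.character(pair)))
    if (length(pair) != 2) stop("a pair task needs two distinct categories")
    return(structure(list(level = "intermediate", classes = pair,
                          chance = 0.5),
                     class = "classification_task"))
  }
  level <- match.arg(level)
  n_classes <- c(superordinate = 2, intermediate = 4, subordinate = 12)[[level]]
  structure(list(level = level, classes = NULL, chance = 1 / n_classes),
            class = "classification_task")
}

#' All pairwise tasks over the four intermediate categories
#'
#' @param tree Taxonomy tibble.
#' @return A named list of 6 [classification_task()] objects, one per
#'   unordered pair of intermediate categories.
#' @export
make_pairwise_tasks <- function(tree) {
  validate_taxonomy(tree)
  cats <- sort(unique(tree$intermediate))
  if (length(cats) != 4) stop("expected 4 intermediate categories, got ",
                              length(cats))
  pairs <- combn(cats, 2, simplify = FALSE)
  tasks <- purrr::map(pairs, ~ classification_task(pair = .x))
  names(tasks) <- purrr::map_chr(pairs, paste, collapse = "-")
  tasks
}

#' Z-score event betas voxel-wise
#'
#' Standardizes each voxel's betas to mean 0, sd 1 across all events, within
#' participant. Zero-variance voxels are clamped (sd treated as 1) with a
#' warning.
#'
#' @param betas Event-pattern tibble with a matrix column `beta` (and,
#'   optionally, a `participant` column; standardization is per
#'   participant).
#' @return The tibble with `beta` standardized.
#' @export
zscore_events <- function(betas) {
  zs <- function(m) {
    if (nrow(m) < 2) stop("z-scoring needs at least 2 events")
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    if (any(s == 0)) {
      warning("zero-variance voxel(s); sd clamped to 1")
      s[s == 0] <- 1
    }
    sweep(sweep(m, 2, mu), 2, s, "/")
  }
  if ("participant" %in% names(betas)) {
    betas |>
      dplyr::group_by(.data$participant) |>
      dplyr::group_modify(function(df, key) { df$beta <- zs(df$beta); df }) |>
      dplyr::ungroup()
  } else {
    betas$beta <- zs(betas$beta)
    betas
  }
}

#' Average event betas into per-run condition patterns
#'
#' Computes, for every run and decoded category, the mean voxel pattern over
#' that category's events in that run. For a pair task, events of the other
#' categories are excluded before averaging.
#'
#' @param betas Event-pattern tibble (see [simulate_event_patterns()]).
#' @param task A [classification_task()].
#' @return A tibble with columns `participant` (if present), `run`,
#'   `condition`, and matrix column `pattern`; exactly one row per
#'   (participant, run, condition).
#' @export
average_conditions <- function(betas, task) {
  stopifnot(inherits(task, "classification_task"))
  lab <- betas[[task$level]]
  if (is.null(lab)) stop("betas lack a '", task$level, "' label column")
  keep <- if (is.null(task$classes)) rep(TRUE, nrow(betas)) else
    lab %in% task$classes
  df <- betas[keep, , drop = FALSE]
  df$condition <- df[[task$level]]

  grp <- intersect(c("participant", "run", "condition"), names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(pattern = list(colMeans(d$beta)))
    }) |>
    dplyr::ungroup()
  out$pattern <- do.call(rbind, out$pattern)

  # every (participant, run) must contain every condition
  conds <- sort(unique(out$condition))
  expected <- if (is.null(task$classes)) conds else sort(task$classes)
  chk <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grp, "condition")))) |>
    dplyr::summarise(ok = setequal(.data$condition, expected),
                     .groups = "drop")
  if (!all(chk$ok))
    stop("missing condition(s) in at least one run; every run must contain ",
         "every decoded category")
  out
}

#' Min-max scale training patterns to [-1, 1] and apply to test
#'
#' Fits, per voxel, the affine map sending the training minimum to -1 and
#' maximum to +1, and applies the same map to the test patterns (test values
#' may fall outside `[-1, 1]`; they are not clipped). Constant training
#' voxels map to 0 with a warning.
#'
#' @param train_patterns,test_patterns Pattern x voxel numeric matrices.
#' @return A list with elements `train` and `test`.
#' @export
scale_train_apply_test <- function(train_patterns, test_patterns) {
  if (ncol(train_patterns) != ncol(test_patterns))
    stop("train and test voxel dimensions differ")
  lo <- apply(train_patterns, 2, min)
  hi <- apply(train_patterns, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning("constant training voxel(s); mapped to 0")
    rng[flat] <- 1
  }
  scale1 <- function(m) {
    m <- sweep(sweep(m, 2, lo), 2, rng, "/") * 2 - 1
    m[, flat] <- 0
    m
  }
  list(train = scale1(train_patterns), test = scale1(test_patterns))
}

# Internal: assemble per-fold scaled train/test matrices for one
# participant's condition patterns. Labels are not needed here because the
# min-max scaling depends only on the train patterns.
build_folds <- function(patterns) {
  runs <- sort(unique(patterns$run))
  if (length(runs) < 2) stop("leave-one-run-out needs >= 2 runs")
  purrr::map(runs, function(r) {
    tr <- patterns[patterns$run != r, , drop = FALSE]
    te <- patterns[patterns$run == r, , drop = FALSE]
    sc <- scale_train_apply_test(tr$pattern, te$pattern)
    list(run = r, train = sc$train, test = sc$test,
         train_cond = tr$condition, test_cond = te$condition,
         train_rows = which(patterns$run != r),
         test_rows = which(patterns$run == r))
  })
}

#' Leave-one-run-out cross-validated decoding
#'
#' Trains a linear soft-margin support-vector classifier (C-SVC, one-vs-one
#' with majority vote for multiclass; vote ties resolved toward the
#' alphabetically first class) on the condition patterns of all runs but
#' one and tests on the held-out run, cycling over runs. Per-condition
#' accuracy is the fraction of that condition's held-out patterns (one per
#' fold) classified correctly; the mean accuracy is the mean over
#' conditions, so with 4 runs and n conditions the achievable means are
#' multiples of 1/(4n).
#'
#' @param patterns Condition patterns of a single participant, from
#'   [average_conditions()].
#' @param task The [classification_task()] (used for the chance level;
#'   optional).
#' @param cost Soft-margin cost parameter C (default 1).
#' @return An object of class `decoding_result`: a list with
#'   `per_condition_accuracy`, `mean_accuracy`, `confusion` (true x
#'   predicted counts), `n_folds`, `conditions`, `chance`.
#' @export
loro_cv_decode <- function(patterns, task = NULL, cost = 1) {
  if ("participant" %in% names(patterns) &&
      length(unique(patterns$participant)) > 1)
    stop("loro_cv_decode() decodes one participant; use decode_participants()")
  conds <- sort(unique(patterns$condition))
  folds <- build_folds(patterns)
  confusion <- matrix(0L, length(conds), length(conds),
                      dimnames = list(true = conds, predicted = conds))
  for (f in folds) {
    ytr <- match(f$train_cond, conds)
    pred <- svc_train_predict(f$train, as.integer(ytr), f$test, cost)
    for (i in seq_along(pred)) {
      confusion[f$test_cond[i], conds[pred[i]]] <-
        confusion[f$test_cond[i], conds[pred[i]]] + 1L
    }
  }
  per_cond <- diag(confusion) / rowSums(confusion)
  structure(list(per_condition_accuracy = per_cond,
                 mean_accuracy = mean(per_cond),
                 confusion = confusion,
                 n_folds = length(folds),
                 conditions = conds,
                 chance = if (!is.null(task)) task$chance else
                   1 / length(conds)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Leave-one-run-out decoding (", length(x$conditions), " classes, ",
      x$n_folds, " folds)\n", sep = "")
  cat("  mean accuracy:", format(x$mean_accuracy, digits = 4),
      "(chance", format(x$chance, digits = 3), ")\n")
  cat("  per condition:",
      paste(names(x$per_condition_accuracy),
            format(x$per_condition_accuracy, digits = 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Decode every participant of a cohort
#'
#' Runs [average_conditions()] and [loro_cv_decode()] for each participant.
#'
#' @param betas Z-scored event-pattern tibble for the whole cohort.
#' @param task A [classification_task()].
#' @param cost Soft-margin cost C.
#' @return A tibble with columns `participant`, `accuracy`, and a list
#'   column `result` of `decoding_result` objects.
#' @export
decode_participants <- function(betas, task, cost = 1) {
  patt <- average_conditions(betas, task)
  patt |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(function(df, key) {
      res <- loro_cv_decode(df, task, cost = cost)
      tibble::tibble(participant = key$participant,
                     accuracy = res$mean_accuracy, result = list(res))
    }) |>
    dplyr::bind_rows()
}
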
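#' Permutation null distribution for one participant
#'
#' Re-runs the full decoding pipeline `n_perm` times with randomized trial
#' labels. The default (and recommended) scheme permutes the event labels
#' within each run before condition averaging, then re-runs averaging,
#' per-fold scaling and the leave-one-run-out classifier: this preserves
#' the per-run class counts, so the null is label-exchangeable and centers
#' at the theoretical chance level. The alternative `"patterns"` scheme
#' permutes the condition labels of the already-averaged run x condition
#' patterns across all patterns; it is retained for comparison but its
#' training folds become class-imbalanced under permutation, which biases
#' the null below chance and makes the test anti-conservative.
#'
#' The returned accuracy per iteration is the fraction of held-out
#' patterns classified correctly (identical to the mean of per-condition
#' accuracies for the balanced design).
#'
#' @param betas Z-scored event-pattern tibble of one participant (for
#'   `scheme = "events"`), or that participant's condition patterns from
#'   [average_conditions()] (for `scheme = "patterns"`).
#' @param task The [classification_task()] naming the decoded tier (used
#'   to pick the label column under `scheme = "events"`).
#' @param n_perm Number of permutations (the study used 1,000).
#' @param seed Integer seed; the same seed reproduces the same null.
#' @param cost Soft-margin cost C.
#' @param scheme `"events"` (default) or `"patterns"`; see Details.
#' @return Numeric vector of `n_perm` null accuracies.
#' @export
participant_null <- function(betas, task = NULL, n_perm = 1000,
                             seed = 1L, cost = 1,
                             scheme = c("events", "patterns")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (scheme == "patterns") {
    patterns <- betas
    conds <- sort(unique(patterns$condition))
    codes <- match(patterns$condition, conds)
    folds <- build_folds(patterns)
    perms <- with_seed(seed, t(replicate(n_perm, sample(codes))))
    storage.mode(perms) <- "integer"
    return(loro_null_accuracies(
      fold_train = purrr::map(folds, "train"),
      fold_test = purrr::map(folds, "test"),
      train_idx = purrr::map(folds, "train_rows"),
      test_idx = purrr::map(folds, "test_rows"),
      perms = perms, cost = cost
    ))
  }
  if (is.null(task)) stop("scheme = 'events' needs the classification task")
  if ("participant" %in% names(betas) &&
      length(unique(betas$participant)) > 1)
    stop("participant_null() works on one participant at a time")
  lab <- betas[[task$level]]
  keep <- if (is.null(task$classes)) rep(TRUE, nrow(betas)) else
    lab %in% task$classes
  df <- betas[keep, , drop = FALSE]
  conds <- sort(unique(df[[task$level]]))
  codes <- match(df[[task$level]], conds)
  runs <- sort(unique(df$run))
  run_ix <- match(df$run, runs)
  perms <- with_seed(seed, {
    m <- matrix(0L, n_perm, nrow(df))
    for (r in seq_along(runs)) {
      ix <- which(run_ix == r)
      for (i in seq_len(n_perm)) m[i, ix] <- codes[ix][sample.int(length(ix))]
    }
    m
  })
  loro_event_null_accuracies(df$beta, as.integer(run_ix), perms,
                             n_classes = length(conds), cost = cost)
}

#' Cohen's d of decoding accuracy against chance
#'
#' `d = (mean(accuracy) - chance) / sd(accuracy)` with the sample (n - 1)
#' standard deviation across participants.
#'
#' @param accuracies Per-participant accuracies.
#' @param chance Chance level of the task.
#' @return The effect size, or `NA` (with a warning) if the accuracies have
#'   zero variance.
#' @export
cohens_d <- function(accuracies, chance) {
  if (length(accuracies) < 2) stop("need >= 2 participants")
  s <- stats::sd(accuracies)
  if (s == 0) {
    warning("zero variance across participants; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(accuracies) - chance) / s
}

#' Group-level permutation test of decoding accuracy
#'
#' Builds the group null by averaging, across participants, the aligned
#' permutation iterations of their individual null distributions, and
#' locates the observed group-mean accuracy in that null. The primary
#' p-value uses the add-one correction `(#{null >= observed} + 1) /
#' (n_perm + 1)`; the uncorrected counting rule (the probability of a null
#' group mean at least as large as the observed one) is reported alongside
#' as `p_literal`. Decoding is declared significant when the observed value
#' lies in the top `alpha` tail of the null.
#'
#' @param observed Per-participant correct-label accuracies.
#' @param nulls Participant x n_perm matrix of null accuracies; row i must
#'   belong to participant i of `observed`, and iteration j must be aligned
#'   across participants.
#' @param chance Chance level (for the effect size); may be `NULL`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_permutation`: a list with
#'   `observed_group_mean`, `null_group_means`, `p_value`, `p_literal`,
#'   `cohens_d`, `n_perm`, `alpha`, `significant`, `n_participants`.
#' @export
group_test <- function(observed, nulls, chance = NULL, alpha = 0.05) {
  nulls <- as.matrix(nulls)
  if (nrow(nulls) != length(observed))
    stop("nulls has ", nrow(nulls), " rows but there are ",
         length(observed), " observed accuracies; participants must match")
  n_perm <- ncol(nulls)
  null_group <- colMeans(nulls)
  obs <- mean(observed)
  p <- (sum(null_group >= obs) + 1) / (n_perm + 1)
  p_lit <- mean(null_group >= obs)
  d <- if (!is.null(chance)) cohens_d(observed, chance) else NA_real_
  structure(list(observed_group_mean = obs,
                 null_group_means = null_group,
                 p_value = p, p_literal = p_lit,
                 cohens_d = d, n_perm = n_perm, alpha = alpha,
                 significant = p <= alpha,
                 chance = chance,
                 n_participants = length(observed)),
            class = "group_permutation")
}

#' @export
print.group_permutation <- function(x, ...) {
  cat("Group permutation test (", x$n_participants, " participants, ",
      x$n_perm, " permutations)\n", sep = "")
  cat("  observed group mean:", format(x$observed_group_mean, digits = 4),
      "\n  null mean:", format(mean(x$null_group_means), digits = 4),
      "\n  P =", format(x$p_value, digits = 3),
      "(literal", format(x$p_literal, digits = 3), ")",
      "\n  Cohen's d =", format(x$cohens_d, digits = 3),
      if (isTRUE(x$significant)) "  *above chance*" else "", "\n")
  invisible(x)
}

#' Pool pairwise accuracies into human and nonhuman pairs
#'
#' Averages, per participant, the three pairwise classification accuracies
#' whose pair contains the human category, and the three that do not.
#'
#' @param pairwise_results Tibble with columns `participant`, `pair`
#'   (e.g. `"animals-humans"`), `accuracy`; all 6 pairs per participant.
#' @param human_label Name of the human category (default `"humans"`).
#' @return Tibble with columns `participant`, `human_pairs`,
#'   `nonhuman_pairs`.
#' @export
pool_human_nonhuman <- function(pairwise_results, human_label = "humans") {
  need <- c("participant", "pair", "accuracy")
  if (!all(need %in% names(pairwise_results)))
    stop("pairwise_results needs columns ", paste(need, collapse = ", "))
  counts <- table(pairwise_results$participant)
  if (any(counts != 6))
    stop("every participant needs all 6 pairwise results")
  pairwise_results |>
    dplyr::mutate(group = ifelse(grepl(human_label, .data$pair, fixed = TRUE),
                                 "human_pairs", "nonhuman_pairs")) |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "accuracy")
}

#' Univariate region-of-interest statistics
#'
#' Tests whether the mean beta of each sound category differs from baseline:
#' betas are averaged over voxels and events within participant and
#' category, then a one-sample t-test across participants is run per
#' category (and region, if a `roi` column is present), with
#' Benjamini-Hochberg adjustment over the whole family of tests.
#'
#' @param betas Event-pattern tibble (cohort).
#' @param level Tier whose categories are compared (default
#'   `"superordinate"`).
#' @param mu Baseline value (default 0).
#' @return Tibble with one row per (roi x) condition: `mean_beta`, `t`,
#'   `df`, `p`, `p_adj`.
#' @export
univariate_roi_stats <- function(betas, level = "superordinate", mu = 0) {
  if (length(unique(betas$participant)) < 2)
    stop("need >= 2 participants")
  grp <- intersect(c("roi", "participant"), names(betas))
  per_part <- betas |>
    dplyr::mutate(condition = .data[[level]]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "condition")))) |>
    dplyr::group_modify(function(d, key)
      tibble::tibble(mean_beta = mean(d$beta))) |>
    dplyr::ungroup()
  out <- per_part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(intersect("roi", grp), "condition")))) |>
    dplyr::summarise(
      mean = mean(.data$mean_beta),
      t = t.test(.data$mean_beta, mu = mu)$statistic,
      df = t.test(.data$mean_beta, mu = mu)$parameter,
      p = t.test(.data$mean_beta, mu = mu)$p.value,
      .groups = "drop")
  names(out)[names(out) == "mean"] <- "mean_beta"
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Correlate imagery vividness with decoding accuracy
#'
#' Pearson correlation between per-participant questionnaire scores
#' (1-5 scale means; higher = less vivid imagery) and decoding accuracies,
#' per region of interest, with Benjamini-Hochberg adjustment across
#' regions. Reported with the `r(df)` convention, `df = n - 2`.
#'
#' @param data Tibble with columns `roi`, `vviq`, `accuracy` (one row per
#'   participant x roi), or `vviq`/`accuracy` only for a single region.
#' @return Tibble with one row per region: `r`, `df`, `p`, `p_adj`.
#' @export
vviq_correlation <- function(data) {
  if (!all(c("vviq", "accuracy") %in% names(data)))
    stop("data needs columns vviq and accuracy")
  if (!"roi" %in% names(data)) data$roi <- "roi"
  out <- data |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need >= 3 paired observations")
      if (stats::sd(d$vviq) == 0 || stats::sd(d$accuracy) == 0) {
        warning("constant input; correlation undefined for region ",
                key$roi)
        return(tibble::tibble(r = NA_real_, df = nrow(d) - 2L,
                              p = NA_real_))
      }
      ct <- cor.test(d$vviq, d$accuracy)
      tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                     p = ct$p.value)
    }) |>
    dplyr::ungroup()
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
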
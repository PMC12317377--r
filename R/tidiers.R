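#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding result
#'
#' One row per decoded condition with its cross-validated accuracy.
#'
#' @param x A `decoding_result` from [loro_cv_decode()].
#' @param ... Unused.
#' @return Tibble with columns `condition`, `accuracy`, `n_folds`.
#' @export
tidy.decoding_result <- function(x, ...) {
  tibble::tibble(condition = names(x$per_condition_accuracy),
                 accuracy = unname(x$per_condition_accuracy),
                 n_folds = x$n_folds)
}

#' @rdname tidy.decoding_result
#' @return For `glance()`: a one-row tibble with `mean_accuracy`, `chance`,
#'   `n_conditions`, `n_folds`.
#' @export
glance.decoding_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, chance = x$chance,
                 n_conditions = length(x$conditions), n_folds = x$n_folds)
}

#' Tidy a group permutation test
#'
#' @param x A `group_permutation` from [group_test()].
#' @param ... Unused.
#' @return For `tidy()`: the null distribution of group means, one row per
#'   permutation iteration. For `glance()`: a one-row summary with the
#'   observed group mean, p-values, effect size and permutation count.
#' @export
tidy.group_permutation <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$null_group_means),
                 null_group_mean = x$null_group_means)
}

#' @rdname tidy.group_permutation
#' @export
glance.group_permutation <- function(x, ...) {
  tibble::tibble(observed = x$observed_group_mean,
                 null_mean = mean(x$null_group_means),
                 p = x$p_value, p_literal = x$p_literal,
                 d = x$cohens_d, n_perm = x$n_perm,
                 n_participants = x$n_participants, alpha = x$alpha,
                 significant = x$significant)
}
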
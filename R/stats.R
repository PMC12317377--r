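#' Power of the one-sample t-test
#'
#' Exact power from the noncentral t distribution: with effect size `d`,
#' sample size `n` and significance level `alpha`, the test statistic under
#' the alternative follows a noncentral t with `df = n - 1` and
#' noncentrality `d * sqrt(n)`.
#'
#' @param d Standardized effect size (Cohen's d), `>= 0`.
#' @param n Sample size (`>= 2`).
#' @param alpha Significance level (default 0.05).
#' @param tail `"one"` (directional, the default: decoding must exceed
#'   chance) or `"two"`.
#' @return Power as a probability.
#' @examples
#' power_one_sample_t(d = 0.6, n = 18)  # ~0.79
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05,
                               tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (d < 0) stop("d must be >= 0")
  if (n < 2) stop("n must be >= 2")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tail == "one") {
    tcrit <- qt(1 - alpha, df)
    pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    tcrit <- qt(1 - alpha / 2, df)
    pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      pt(-tcrit, df, ncp = ncp)
  }
}

#' Smallest sample size reaching a target power
#'
#' @inheritParams power_one_sample_t
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param n_max Search cap (default 10^6).
#' @return The smallest integer `n` with
#'   `power_one_sample_t(d, n, alpha, tail) >= target_power`.
#' @examples
#' min_n_for_power(d = 0.6, target_power = 0.80)  # 19
#' @export
min_n_for_power <- function(d, alpha = 0.05, tail = c("one", "two"),
                            target_power = 0.80, n_max = 1e6) {
  tail <- match.arg(tail)
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must be in (alpha, 1)")
  if (d <= 0) stop("d must be > 0")
  for (n in 2:n_max) {
    if (power_one_sample_t(d, n, alpha, tail) >= target_power) return(n)
  }
  stop("no n <= ", n_max, " reaches the target power")
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares decomposition over `k` groups;
#' `df = (k - 1, N - k)`.
#'
#' @param groups A list of numeric vectors (one per group), or a data frame
#'   with columns `value` and `group`.
#' @return Tibble with columns `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  n <- lengths(groups)
  N <- sum(n)
  if (N <= k) stop("need more observations than groups")
  if (length(unique(n)) > 1)
    warning("unequal group sizes; df computed accordingly")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), n))
  grand <- mean(values)
  ss_between <- sum(n * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ss_within == 0) {
    warning("zero within-group variance; F is infinite")
    return(tibble::tibble(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  F_stat <- (ss_between / df1) / (ss_within / df2)
  tibble::tibble(F = F_stat, df1 = df1, df2 = df2,
                 p = stats::pf(F_stat, df1, df2, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] kept for a stable pipeline surface).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, `>=` raw, `<= 1`).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return Tibble with columns `r`, `df` (`= n - 2`), `p` (two-sided).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value)
}
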
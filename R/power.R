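# A-priori power analysis for the paired (one-sample) t-test on
# within-subject differences, via the noncentral t distribution.

#' Power of a two-sided paired t-test
#'
#' With `n` pairs, effect size Cohen's dz, and two-sided significance level
#' alpha, the test statistic follows a noncentral t distribution with
#' `n - 1` degrees of freedom and noncentrality `dz * sqrt(n)`. Power is
#' the probability mass of that distribution beyond the two-sided critical
#' values. At `dz = 0` the power equals alpha.
#'
#' @param n Number of pairs (integer, at least 2).
#' @param effect_size Cohen's dz (mean difference / SD of differences).
#' @param alpha Two-sided significance level (default 0.05).
#'
#' @return Power in (0, 1).
#' @export
#' @examples
#' achieved_power(19, 0.7)  # >= 0.8
achieved_power <- function(n, effect_size, alpha = 0.05) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  df <- n - 1L
  ncp <- effect_size * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}

#' Required sample size for a paired two-sided t-test
#'
#' The smallest `n >= 2` whose [achieved_power()] reaches the target.
#'
#' @param effect_size Cohen's dz; must be positive.
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @param n_max Search cap (default 1e5).
#'
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(0.7, 0.05, 0.8)  # 19
required_sample_size <- function(effect_size, alpha = 0.05, power = 0.8,
                                 n_max = 1e5L) {
  if (effect_size <= 0) stop("effect_size must be positive")
  if (power <= 0 || power >= 1) stop("target power must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  for (n in 2:n_max)
    if (achieved_power(n, effect_size, alpha) >= power) return(as.integer(n))
  stop("no n <= n_max reaches the target power")
}
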
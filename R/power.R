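#' Power of a fixed-effects one-way ANOVA F test
#'
#' Power is computed from the noncentral F distribution with
#' `df1 = k - 1`, `df2 = N - k` and noncentrality `lambda = f^2 * N`
#' (total-sample-size convention for Cohen's f, as used by standard
#' a-priori sample-size software).
#'
#' @param N total sample size across all groups.
#' @param f Cohen's f effect size (> 0); f = 0.5 is conventionally "large".
#' @param alpha type-I error rate.
#' @param k number of groups.
#' @return achieved power, a probability.
#' @examples
#' anova_power(48, f = 0.5, alpha = 0.05, k = 4)  # ~0.80
#' @export
anova_power <- function(N, f, alpha = 0.05, k = 4) {
  stopifnot(f > 0, alpha > 0, alpha < 1, k >= 2)
  if (N <= k) stop("N must exceed the number of groups")
  df1 <- k - 1
  df2 <- N - k
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f^2 * N, lower.tail = FALSE)
}

#' Minimal total sample size reaching a target ANOVA power
#'
#' Smallest integer `N >= k + 1` whose one-way fixed-effects ANOVA power
#' ([anova_power()]) reaches `target_power`.
#'
#' @param f Cohen's f effect size.
#' @param alpha type-I error rate.
#' @param target_power required power.
#' @param k number of groups.
#' @return integer total sample size.
#' @examples
#' min_total_n(f = 0.5, alpha = 0.05, target_power = 0.8, k = 4)  # 48
#' @export
min_total_n <- function(f, alpha = 0.05, target_power = 0.8, k = 4) {
  stopifnot(target_power > 0, target_power < 1)
  N <- k + 1
  while (anova_power(N, f, alpha, k) < target_power) {
    N <- N + 1
    if (N > 1e6) stop("no attainable sample size below 1e6")
  }
  as.integer(N)
}
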
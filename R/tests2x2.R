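# The three hypothesis tests applied to the survivor 2x2 table: Pearson
# chi-squared without continuity correction, its 'N-1' small-sample variant,
# and Fisher's exact test. The chi-squared tests are incomputable when a row
# or column margin is zero (an expected count of zero); the caller records a
# missing statistic rather than aborting the run.

chi2_statistic <- function(tab) {
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  N <- a + b + cc + d
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  if (denom == 0) return(NA_real_)
  N * (a * d - b * cc)^2 / denom
}

#' Pearson chi-squared test on a survivor 2x2 table
#'
#' The uncorrected Pearson statistic
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` referred to the upper tail
#' of a chi-squared(1) distribution. No Yates continuity correction is
#' applied: the 'N-1' variant ([n1_chi_squared_test()]) is defined relative
#' to the uncorrected statistic. Returns `NA` when any row (arm) or column
#' (event) margin is zero, since an expected count is then zero; the
#' performance summaries count these as missing test statistics.
#'
#' @inheritParams detect_separation
#' @return A one-row tibble with columns `statistic` and `p_value` (both
#'   `NA` when incomputable).
#' @examples
#' chi_squared_test(c(10, 40, 20, 30))
#' @export
chi_squared_test <- function(tab) {
  tab <- check_table(tab)
  x2 <- chi2_statistic(tab)
  tibble::tibble(statistic = x2,
                 p_value = if (is.na(x2)) NA_real_ else pchisq(x2, 1, lower.tail = FALSE))
}

#' 'N-1' adjusted chi-squared test
#'
#' Multiplies the uncorrected Pearson statistic by `(N - 1)/N`, where `N` is
#' the total analysable sample size (the survivor subgroup), and refers the
#' result to chi-squared(1). Recommended for small samples; converges to the
#' plain Pearson test as `N` grows. Incomputable under the same zero-margin
#' rule as [chi_squared_test()].
#'
#' @inheritParams detect_separation
#' @return A one-row tibble with columns `statistic` and `p_value`.
#' @examples
#' n1_chi_squared_test(c(10, 40, 20, 30))
#' @export
n1_chi_squared_test <- function(tab) {
  tab <- check_table(tab)
  x2 <- chi2_statistic(tab)
  N <- sum(tab)
  stat <- if (is.na(x2) || N == 0) NA_real_ else x2 * (N - 1) / N
  tibble::tibble(statistic = stat,
                 p_value = if (is.na(stat)) NA_real_ else pchisq(stat, 1, lower.tail = FALSE))
}

#' Fisher's exact test on a survivor 2x2 table
#'
#' Two-sided exact test conditioning on the observed margins, using the
#' probability-mass convention: the p-value sums the hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table. Always computable; with a zero
#' column margin only one table is consistent with the margins and p = 1.
#' Delegates to [stats::fisher.test()].
#'
#' @inheritParams detect_separation
#' @return A one-row tibble with column `p_value`.
#' @examples
#' fisher_exact_test(c(1, 9, 9, 1))
#' @export
fisher_exact_test <- function(tab) {
  tab <- check_table(tab)
  p <- stats::fisher.test(matrix(tab, 2, 2, byrow = TRUE))$p.value
  tibble::tibble(p_value = min(p, 1))
}
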
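# Profile-likelihood confidence interval for the log odds ratio of a 2x2
# table. The model is two independent binomials with logits (mu + psi, mu);
# for each fixed psi the intercept mu is profiled out by Newton iteration on
# the score, and the CI endpoints solve
#   2 * (loglik_max - profile_loglik(psi)) = qchisq(level, 1)
# by bisection, bracketed between the MLE and MLE +/- 10 Wald SEs.

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

# Binomial log-likelihood at logits (mu + psi) for the treated arm and mu
# for the control arm.
ll_2x2 <- function(mu, psi, a, n1, c, n0) {
  eta1 <- mu + psi
  a * eta1 - n1 * log1pexp(eta1) + c * mu - n0 * log1pexp(mu)
}

# Profile log-likelihood over the intercept at fixed log-OR psi.
profile_ll <- function(psi, a, n1, c, n0, tol = 1e-12, max_iter = 100L) {
  mu <- qlogis((c + 0.5) / (n0 + 1))   # start near the control-arm logit
  for (i in seq_len(max_iter)) {
    p1 <- plogis(mu + psi)
    p0 <- plogis(mu)
    score <- (a + c) - n1 * p1 - n0 * p0
    info <- n1 * p1 * (1 - p1) + n0 * p0 * (1 - p0)
    if (info <= 0) break
    step <- score / info
    mu <- mu + step
    if (abs(step) < tol) break
  }
  ll_2x2(mu, psi, a, n1, c, n0)
}

#' Profile-likelihood confidence interval for a 2x2 log odds ratio
#'
#' Computes the interval whose endpoints are the two values of the treatment
#' log odds ratio at which twice the drop from the maximised binomial
#' log-likelihood (profiling out the intercept at each fixed log-OR) equals
#' the chi-squared(1) quantile for the requested level. Endpoints are found
#' by bisection between the MLE and MLE +/- 10 Wald standard errors,
#' refined until the deviance condition holds to within `tol`; the interval
#' strictly contains the MLE.
#'
#' @inheritParams detect_separation
#' @param level Confidence level (default 0.95).
#' @param tol Absolute tolerance on the deviance condition at each endpoint
#'   (default 1e-8).
#' @return A one-row tibble with columns `ci_low` and `ci_high` on the
#'   log-OR scale.
#' @examples
#' profile_likelihood_ci(c(10, 40, 5, 45))
#' @export
profile_likelihood_ci <- function(tab, level = 0.95, tol = 1e-8) {
  tab <- check_table(tab)
  if (any(tab == 0)) {
    abort("Table is separated: profile interval undefined.",
          class = "truncsim_separation")
  }
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "truncsim_invalid_parameter")
  }
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  n1 <- a + b; n0 <- cc + d
  psi_hat <- log(a * d / (b * cc))
  se <- sqrt(sum(1 / tab))
  # Saturated maximum: fitted probabilities equal observed proportions.
  ll_max <- a * log(a / n1) + b * log(b / n1) + cc * log(cc / n0) + d * log(d / n0)
  q <- qchisq(level, 1)
  dev <- function(psi) 2 * (ll_max - profile_ll(psi, a, n1, cc, n0)) - q

  solve_endpoint <- function(direction) {
    lo <- psi_hat
    hi <- psi_hat + direction * 10 * se
    f_hi <- dev(hi)
    tries <- 0L
    while (f_hi < 0 && tries < 10L) {  # widen if 10 SEs do not bracket
      hi <- hi + direction * 10 * se
      f_hi <- dev(hi)
      tries <- tries + 1L
    }
    if (f_hi < 0) {
      abort(sprintf(
        "Failed to bracket the %s profile endpoint (psi_hat = %.4g, se = %.4g).",
        if (direction > 0) "upper" else "lower", psi_hat, se),
        class = "truncsim_numerical")
    }
    for (i in seq_len(300L)) {
      mid <- (lo + hi) / 2
      f_mid <- dev(mid)
      if (abs(f_mid) < tol) return(mid)
      if (f_mid < 0) lo <- mid else hi <- mid
    }
    mid
  }

  tibble::tibble(ci_low = solve_endpoint(-1), ci_high = solve_endpoint(1))
}
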
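# Independent oracles used across the test files. Each re-derives the
# quantity by a route disjoint from the package implementation: direct
# enumeration, a maximum-likelihood fit, or a dense grid search.

# Two-sided Fisher p-value by exhaustive enumeration over the
# hypergeometric support (probability-mass convention, with the standard
# relative tolerance for ties).
fisher_enum_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c          # total events
  n1 <- a + b         # treated margin
  support <- max(0, K - (N - n1)):min(K, n1)
  probs <- dhyper(support, K, N - K, n1)
  p_obs <- dhyper(a, K, N - K, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log OR and Wald SE from an iteratively fitted logistic regression on the
# expanded individual-level data.
glm_logor_oracle <- function(a, b, c, d) {
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  x <- c(rep(1, a + b), rep(0, c + d))
  fit <- stats::glm(y ~ x, family = stats::binomial())
  c(log_or = unname(stats::coef(fit)["x"]),
    se = unname(sqrt(stats::vcov(fit)["x", "x"])))
}

# Profile deviance of the 2x2 log OR at fixed psi, profiling the intercept
# by stats::optimize (independent of the package's Newton solver).
profile_dev_oracle <- function(psi, a, b, c, d) {
  n1 <- a + b; n0 <- c + d
  ll <- function(mu) {
    eta1 <- mu + psi
    a * eta1 - n1 * log1p(exp(pmin(eta1, 700))) + c * mu - n0 * log1p(exp(pmin(mu, 700)))
  }
  opt <- stats::optimize(ll, lower = -30, upper = 30, maximum = TRUE,
                         tol = 1e-12)
  ll_max <- a * log(a / n1) + b * log(b / n1) + c * log(c / n0) + d * log(d / n0)
  2 * (ll_max - opt$objective)
}

# Random non-separated 2x2 table with margins up to max_n per arm.
random_table <- function(max_n = 60) {
  repeat {
    n1 <- sample(2:max_n, 1)
    n0 <- sample(2:max_n, 1)
    a <- stats::rbinom(1, n1, stats::runif(1, 0.1, 0.9))
    c <- stats::rbinom(1, n0, stats::runif(1, 0.1, 0.9))
    tab <- c(a = a, b = n1 - a, c = c, d = n0 - c)
    if (all(tab > 0)) return(tab)
  }
}

core_continuous_params <- function(n, or_intermediate, beta_r_sd,
                                   n_iterations = 10000) {
  scenario_params(n = n, family = "continuous",
                  alpha_R = log(or_intermediate),
                  beta_R = beta_r_sd * 580, n_iterations = n_iterations)
}

core_binary_params <- function(n, or_intermediate, or_outcome,
                               n_iterations = 10000) {
  scenario_params(n = n, family = "binary",
                  alpha_R = log(or_intermediate),
                  beta_R = log(or_outcome), n_iterations = n_iterations)
}
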
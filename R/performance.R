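# Monte-Carlo performance measures against the hypothetical estimand, with
# Monte-Carlo standard errors. Estimate-based measures use only the
# estimable iterations; rejection rates support both denominator
# conventions (computable-only and all-iterations).

#' Monte-Carlo bias
#'
#' Mean of the estimates minus the true estimand value. For continuous
#' scenarios the caller typically also reports bias in SD units (divide by
#' `sigma`).
#'
#' @param estimates Numeric vector of estimates (estimable iterations only).
#' @param truth True estimand value on the same scale.
#' @return A single number.
#' @examples
#' bias(c(4, 5, 6), 5)
#' @export
bias <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0) {
    abort("Need at least one estimate.", class = "truncsim_invalid_input")
  }
  mean(estimates) - truth
}

#' Ratio of estimated to true odds ratio (ROR)
#'
#' The binary study's bias measure, computed over non-separated iterations
#' only. Two conventions are supported. The default, `"mean_or"`, averages
#' the estimated odds ratios themselves and divides by the true OR,
#' `mean(exp(log_or)) / exp(truth_log_or)`; because the sampling
#' distribution of the OR is right-skewed this can sit well above 1 in
#' small survivor subgroups even when the mean log-OR bias is modest.
#' `"geometric"` exponentiates the mean log-OR bias,
#' `exp(mean(log_or) - truth_log_or)`, i.e. the geometric-mean ratio.
#'
#' @param log_or_estimates Numeric vector of estimated log odds ratios.
#' @param truth_log_or True log odds ratio.
#' @param method `"mean_or"` (default) or `"geometric"`.
#' @return A positive number; 1 means no bias on the OR scale.
#' @examples
#' ror(c(0.1, 0.3), 0.1)
#' ror(c(0.1, 0.3), 0.1, method = "geometric")
#' @export
ror <- function(log_or_estimates, truth_log_or,
                method = c("mean_or", "geometric")) {
  method <- match.arg(method)
  if (method == "geometric") {
    exp(bias(log_or_estimates, truth_log_or))
  } else {
    lo <- log_or_estimates[!is.na(log_or_estimates)]
    if (length(lo) == 0) {
      abort("Need at least one estimate.", class = "truncsim_invalid_input")
    }
    mean(exp(lo)) / exp(truth_log_or)
  }
}

#' Empirical standard error of the estimates
#'
#' Sample standard deviation (divisor `n - 1`) of the estimable estimates
#' across Monte-Carlo repetitions.
#'
#' @param estimates Numeric vector of estimates.
#' @return A non-negative number.
#' @examples
#' empirical_se(c(1, 2, 3))
#' @export
empirical_se <- function(estimates) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) < 2) {
    abort("Need at least two estimates.", class = "truncsim_invalid_input")
  }
  sd(estimates)
}

#' Average model-based standard error
#'
#' Root-mean-square of the within-trial standard errors over estimable
#' iterations (the convention under which the model SE is comparable with
#' the empirical SE); an arithmetic-mean variant is available for
#' sensitivity.
#'
#' @param model_ses Numeric vector of per-iteration model standard errors.
#' @param method `"rms"` (default) or `"mean"`.
#' @return A positive number.
#' @examples
#' model_se(c(3, 4))
#' @export
model_se <- function(model_ses, method = c("rms", "mean")) {
  method <- match.arg(method)
  model_ses <- model_ses[!is.na(model_ses)]
  if (length(model_ses) == 0) {
    abort("Need at least one model SE.", class = "truncsim_invalid_input")
  }
  if (method == "rms") sqrt(mean(model_ses^2)) else mean(model_ses)
}

#' Empirical coverage of confidence intervals
#'
#' Proportion of computable intervals containing the true estimand; the
#' denominator is the number of computable intervals (rows where both
#' endpoints are non-missing).
#'
#' @param ci_low,ci_high Numeric vectors of interval endpoints; `NA` marks
#'   an incomputable interval.
#' @param truth True estimand value.
#' @return A probability.
#' @examples
#' coverage(c(0, 1, 5), c(2, 3, 6), 1.5)
#' @export
coverage <- function(ci_low, ci_high, truth) {
  ok <- !is.na(ci_low) & !is.na(ci_high)
  if (!any(ok)) {
    abort("No computable intervals.", class = "truncsim_invalid_input")
  }
  mean(ci_low[ok] <= truth & truth <= ci_high[ok])
}

#' Rejection rate of a test across Monte-Carlo repetitions
#'
#' Proportion of p-values below `alpha`. Under the default
#' `denominator = "computable"` convention, iterations with an incomputable
#' statistic (`NA` p-value) are excluded from the denominator; under
#' `"all"`, they count as non-rejections, which deflates the rate when
#' incomputability is common (as in small truncated binary trials). Under a
#' null treatment effect this is the type-1 error.
#'
#' @param p_values Numeric vector of p-values, `NA` for incomputable tests.
#' @param alpha Significance level (default 0.05).
#' @param denominator `"computable"` (default) or `"all"`.
#' @return A probability (NA if no p-value is computable under
#'   `"computable"`).
#' @examples
#' rejection_rate(c(0.01, 0.2, NA), denominator = "all")
#' @export
rejection_rate <- function(p_values, alpha = 0.05,
                           denominator = c("computable", "all")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(p_values)
  if (denominator == "computable") {
    if (!any(ok)) return(NA_real_)
    mean(p_values[ok] < alpha)
  } else {
    sum(p_values[ok] < alpha) / length(p_values)
  }
}

mc_se_prop <- function(p, m) if (m > 0 && !is.na(p)) sqrt(p * (1 - p) / m) else NA_real_

#' Summarise a scenario's per-iteration results into performance measures
#'
#' Aggregates the per-iteration analysis records of one scenario into the
#' platform's performance summary against the hypothetical estimand
#' (`beta_R` on the analysis scale): bias (and bias in SD units or the ROR,
#' by family), empirical and model SE, coverage of the confidence interval,
#' rejection rates of each test, and the missingness accounting
#' (`n_estimable + n_separated = n_iterations` for binary scenarios;
#' incomputable test statistics tallied per test). Each measure carries a
#' Monte-Carlo standard error so reduced-replication runs can state
#' tolerance bands.
#'
#' @param records A data frame of per-iteration results as produced by
#'   [analyse_trial()] rows (continuous or binary layout).
#' @param params The [scenario_params()] that generated the records.
#' @param alpha Significance level for rejection rates (default 0.05).
#' @param denominator Rejection-rate denominator convention, passed to
#'   [rejection_rate()].
#' @param se_method Model-SE averaging convention, passed to [model_se()].
#' @param ror_method ROR convention, passed to [ror()] (binary only).
#' @return A one-row tibble; columns not applicable to the family are `NA`.
#'   Key columns: `truth`, `n_iterations`, `n_estimable`, `n_separated`,
#'   `bias`, `bias_mc_se`, `bias_sd_units` (continuous), `ror`, `ror_mc_se`
#'   (binary), `empirical_se`, `model_se`, `coverage`, `coverage_mc_se`,
#'   `rej_t`/`rej_chi2`/`rej_chi2_adj`/`rej_fisher` with `*_mc_se`, and
#'   `n_incomputable_*` tallies.
#' @export
summarise_scenario <- function(records, params, alpha = 0.05,
                               denominator = c("computable", "all"),
                               se_method = c("rms", "mean"),
                               ror_method = c("mean_or", "geometric")) {
  denominator <- match.arg(denominator)
  se_method <- match.arg(se_method)
  ror_method <- match.arg(ror_method)
  validate_scenario_params(params)
  stopifnot(is.data.frame(records))
  m <- nrow(records)
  truth <- params$beta_R
  continuous <- params$family == "continuous"

  est <- if (continuous) records$estimate else records$log_or
  est_ok <- !is.na(est)
  n_est <- sum(est_ok)
  n_sep <- if (continuous) sum(!records$computable) else sum(!records$or_estimable)

  out <- tibble::tibble(
    family = params$family, truth = truth,
    n_iterations = m, n_estimable = n_est, n_separated = n_sep,
    bias = NA_real_, bias_mc_se = NA_real_, bias_sd_units = NA_real_,
    ror = NA_real_, ror_mc_se = NA_real_,
    empirical_se = NA_real_, empirical_se_mc_se = NA_real_,
    model_se = NA_real_,
    coverage = NA_real_, coverage_mc_se = NA_real_,
    rej_t = NA_real_, rej_t_mc_se = NA_real_,
    rej_chi2 = NA_real_, rej_chi2_mc_se = NA_real_,
    rej_chi2_adj = NA_real_, rej_chi2_adj_mc_se = NA_real_,
    rej_fisher = NA_real_, rej_fisher_mc_se = NA_real_,
    n_incomputable_t = NA_integer_, n_incomputable_chi2 = NA_integer_,
    n_incomputable_fisher = NA_integer_
  )

  if (n_est >= 2) {
    b <- bias(est, truth)
    e_se <- empirical_se(est)
    out$bias <- b
    out$bias_mc_se <- e_se / sqrt(n_est)
    out$empirical_se <- e_se
    # MC SE of a sample SD of approximately normal estimates
    out$empirical_se_mc_se <- e_se / sqrt(2 * (n_est - 1))
    out$model_se <- model_se(records$model_se, method = se_method)
    if (continuous) {
      out$bias_sd_units <- b / params$sigma
    } else {
      out$ror <- ror(est, truth, method = ror_method)
      out$ror_mc_se <- if (ror_method == "geometric") {
        exp(b) * out$bias_mc_se
      } else {
        sd(exp(est[est_ok])) / sqrt(n_est) / exp(truth)
      }
    }
  }
  ci_ok <- !is.na(records$ci_low) & !is.na(records$ci_high)
  if (any(ci_ok)) {
    cov <- coverage(records$ci_low, records$ci_high, truth)
    out$coverage <- cov
    out$coverage_mc_se <- mc_se_prop(cov, sum(ci_ok))
  }

  rej <- function(p) {
    r <- rejection_rate(p, alpha, denominator)
    mden <- if (denominator == "all") length(p) else sum(!is.na(p))
    c(r, mc_se_prop(r, mden))
  }
  if (continuous) {
    rr <- rej(records$p_value)
    out$rej_t <- rr[1]; out$rej_t_mc_se <- rr[2]
    out$n_incomputable_t <- sum(is.na(records$p_value))
  } else {
    rr <- rej(records$p_chi2)
    out$rej_chi2 <- rr[1]; out$rej_chi2_mc_se <- rr[2]
    rr <- rej(records$p_chi2_adj)
    out$rej_chi2_adj <- rr[1]; out$rej_chi2_adj_mc_se <- rr[2]
    rr <- rej(records$p_fisher)
    out$rej_fisher <- rr[1]; out$rej_fisher_mc_se <- rr[2]
    out$n_incomputable_chi2 <- sum(is.na(records$p_chi2))
    out$n_incomputable_fisher <- sum(is.na(records$p_fisher))
  }
  out
}
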
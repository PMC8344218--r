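# Internal per-trial binary analysis on plain structures; returns a list.
# Flags rather than errors on separation/degeneracy so scenario runs never
# abort mid-loop.
analyse_binary_core <- function(tab, conf_level = 0.95, compute_ci = TRUE,
                                compute_tests = TRUE) {
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  separated <- any(tab == 0)
  out <- list(log_or = NA_real_, model_se = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              p_chi2 = NA_real_, p_chi2_adj = NA_real_, p_fisher = NA_real_,
              a = a, b = b, c = cc, d = d,
              n_treated = a + b, n_control = cc + d,
              or_estimable = !separated, chi2_computable = FALSE)
  if (!separated) {
    out$log_or <- log(a * d / (b * cc))
    out$model_se <- sqrt(sum(1 / tab))
    if (compute_ci) {
      ci <- profile_likelihood_ci(tab, level = conf_level)
      out$ci_low <- ci$ci_low
      out$ci_high <- ci$ci_high
    }
  }
  if (compute_tests) {
    x2 <- chi2_statistic(tab)
    if (!is.na(x2)) {
      N <- sum(tab)
      out$chi2_computable <- TRUE
      out$p_chi2 <- pchisq(x2, 1, lower.tail = FALSE)
      out$p_chi2_adj <- pchisq(x2 * (N - 1) / N, 1, lower.tail = FALSE)
    }
    out$p_fisher <- min(stats::fisher.test(matrix(tab, 2, 2, byrow = TRUE))$p.value, 1)
  }
  out
}

#' Analyse one trial with the standard uncensored-subgroup methods
#'
#' Truncates the trial to survivors and applies every analysis used for the
#' given outcome family. Continuous: difference in survivor means with
#' pooled-variance t inference. Binary: sample log odds ratio with Wald
#' standard error and profile-likelihood confidence interval, plus the
#' chi-squared, 'N-1' chi-squared and Fisher's exact tests on the survivor
#' 2x2 table. Degenerate configurations (separation, zero margins, fewer
#' than two survivors per arm) never raise: the corresponding statistics are
#' `NA` and the computability flags say why.
#'
#' @param trial A trial data frame with columns `R`, `S`, `Y`.
#' @param family `"continuous"` or `"binary"`; must match the trial's
#'   outcome type.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble. Continuous: `estimate`, `model_se`, `ci_low`,
#'   `ci_high`, `p_value`, `n_treated`, `n_control`, `computable`.
#'   Binary: `log_or`, `model_se`, `ci_low`, `ci_high`, `p_chi2`,
#'   `p_chi2_adj`, `p_fisher`, the table cells `a`, `b`, `c`, `d`,
#'   `n_treated`, `n_control`, `or_estimable`, `chi2_computable`.
#' @examples
#' p <- scenario_params(n = 200, family = "binary", alpha_R = log(1.2),
#'                      beta_R = log(1.2))
#' analyse_trial(simulate_trial(p, seed = 1), "binary")
#' @export
analyse_trial <- function(trial, family = c("continuous", "binary"),
                          conf_level = 0.95) {
  family <- match.arg(family)
  stopifnot(is.data.frame(trial), all(c("R", "S", "Y") %in% names(trial)))
  if (family == "binary" && !all(trial$Y %in% c(0, 1))) {
    abort("`family = 'binary'` but `Y` is not 0/1.",
          class = "truncsim_invalid_state")
  }
  if (family == "continuous" && all(trial$Y %in% c(0, 1)) && nrow(trial) > 2) {
    abort("`family = 'continuous'` but `Y` looks binary.",
          class = "truncsim_invalid_state")
  }
  if (family == "continuous") {
    arms <- split_survivors(trial)
    tibble::as_tibble(diff_means_core(arms$y_treat, arms$y_ctrl, conf_level))
  } else {
    tibble::as_tibble(analyse_binary_core(survivor_table(trial), conf_level))
  }
}
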
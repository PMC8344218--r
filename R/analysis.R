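#' Restrict a trial to the uncensored (survivor) subgroup
#'
#' Drops participants whose intermediate response is 0, i.e. those for whom
#' the outcome is undefined. This is the selection step that breaks
#' randomisation when treatment affects the intermediate.
#'
#' @param trial A trial data frame with columns `R`, `S`, `Y` (as produced
#'   by [simulate_trial()]).
#' @return A tibble containing only rows with `S == 1`. Empty arms are legal
#'   and handled by the downstream analyses.
#' @export
truncate_trial <- function(trial) {
  stopifnot(is.data.frame(trial), all(c("R", "S", "Y") %in% names(trial)))
  tibble::as_tibble(trial[trial$S == 1, , drop = FALSE])
}

# Internal: survivor outcomes split by arm.
split_survivors <- function(trial) {
  keep <- trial$S == 1
  list(y_treat = trial$Y[keep & trial$R == 1],
       y_ctrl  = trial$Y[keep & trial$R == 0])
}

# Core two-sample pooled-variance t analysis on plain vectors; returns a list.
diff_means_core <- function(y_treat, y_ctrl, conf_level = 0.95) {
  n1 <- length(y_treat)
  n0 <- length(y_ctrl)
  if (n1 < 2 || n0 < 2) {
    return(list(estimate = NA_real_, model_se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                n_treated = n1, n_control = n0, computable = FALSE))
  }
  est <- mean(y_treat) - mean(y_ctrl)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * var(y_treat) + (n0 - 1) * var(y_ctrl)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  tstat <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  p <- 2 * pt(-abs(tstat), df)
  tc <- qt(1 - (1 - conf_level) / 2, df)
  list(estimate = est, model_se = se,
       ci_low = est - tc * se, ci_high = est + tc * se, p_value = p,
       n_treated = n1, n_control = n0, computable = TRUE)
}

#' Difference in survivor means with equal-variance t inference
#'
#' The standard unadjusted analysis of a truncated continuous outcome:
#' difference in arm means among survivors, pooled-variance standard error,
#' two-sample equal-variance t-test with `n1 + n0 - 2` degrees of freedom,
#' and a t-based confidence interval. Flagged incomputable (all statistics
#' `NA`) when either arm has fewer than two survivors, since the pooled
#' variance is then undefined; such instances are counted as missing by the
#' performance summaries.
#'
#' @param y_treat,y_ctrl Numeric vectors of survivor outcomes in the treated
#'   and control arm.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble with columns `estimate`, `model_se`, `ci_low`,
#'   `ci_high`, `p_value`, `n_treated`, `n_control`, `computable`.
#' @examples
#' difference_in_means(c(2, 3, 4), c(1, 2, 3))
#' @export
difference_in_means <- function(y_treat, y_ctrl, conf_level = 0.95) {
  if (!is.numeric(y_treat) || !is.numeric(y_ctrl)) {
    abort("`y_treat` and `y_ctrl` must be numeric vectors.",
          class = "truncsim_invalid_input")
  }
  tibble::as_tibble(diff_means_core(y_treat, y_ctrl, conf_level))
}

#' Survivor-subgroup 2x2 arm-by-outcome table
#'
#' Counts outcome events and non-events by arm among survivors (`S == 1`):
#' `a`/`b` are treated-arm events/non-events, `c`/`d` control-arm
#' events/non-events.
#'
#' @param trial A trial data frame with columns `R`, `S`, `Y` and binary `Y`.
#' @return A named numeric vector `c(a, b, c, d)`.
#' @export
survivor_table <- function(trial) {
  keep <- trial$S == 1
  R <- trial$R[keep]
  Y <- trial$Y[keep]
  c(a = sum(R == 1 & Y == 1), b = sum(R == 1 & Y == 0),
    c = sum(R == 0 & Y == 1), d = sum(R == 0 & Y == 0))
}

check_table <- function(tab) {
  if (!is.numeric(tab) || length(tab) != 4 || any(is.na(tab)) ||
      any(tab < 0) || any(tab != floor(tab))) {
    abort("A 2x2 table must be four non-negative integer counts (a, b, c, d).",
          class = "truncsim_invalid_input")
  }
  as.numeric(tab)
}

#' Detect separation in a survivor 2x2 table
#'
#' A table is separated when none or all of the analysable participants in a
#' study arm experience the outcome event, i.e. any of the four cells is
#' zero (this also covers an empty arm). Separated tables leave the odds
#' ratio and its Wald standard error undefined; the performance summaries
#' count them as missing data.
#'
#' @param tab Numeric vector `c(a, b, c, d)` as from [survivor_table()].
#' @return `TRUE` if any cell is zero.
#' @examples
#' detect_separation(c(0, 50, 10, 40))
#' @export
detect_separation <- function(tab) {
  tab <- check_table(tab)
  any(tab == 0)
}

#' Sample log odds ratio and Wald standard error from a 2x2 table
#'
#' The maximum-likelihood estimate of the treatment coefficient in a
#' logistic regression of the outcome on treatment alone is available in
#' closed form on a saturated 2x2 table: `log(a*d / (b*c))`, with Woolf
#' (Wald) standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. Equivalence with the
#' iteratively fitted logistic model is part of the test suite.
#'
#' @inheritParams detect_separation
#' @return A one-row tibble with columns `log_or` and `wald_se`.
#' @examples
#' fit_logistic_or(c(10, 40, 5, 45))
#' @export
fit_logistic_or <- function(tab) {
  tab <- check_table(tab)
  if (any(tab == 0)) {
    abort("Table is separated: a zero cell leaves the odds ratio undefined.",
          class = "truncsim_separation")
  }
  tibble::tibble(
    log_or = log(tab[1] * tab[4] / (tab[2] * tab[3])),
    wald_se = sqrt(sum(1 / tab))
  )
}
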
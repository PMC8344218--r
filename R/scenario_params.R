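#' Parameters for one simulated-trial scenario
#'
#' Bundles the full parameterisation of a single two-arm trial scenario:
#' the sample size, the logistic model for the binary intermediate response
#' \eqn{S} (which gates whether the outcome is observable), and the outcome
#' model (normal for continuous outcomes such as birthweight, logistic for
#' binary outcomes such as miscarriage). A single standard-normal confounder
#' `u` enters both submodels; this shared dependence is what creates selection
#' bias when treatment also affects the intermediate.
#'
#' The intermediate linear predictor is
#' \deqn{logit(\pi_i) = \alpha_0 + \alpha_R R_i + \alpha_U u_i + \alpha_{RU} R_i u_i}
#' and the outcome mean (continuous) or log-odds (binary) is
#' \deqn{\beta_0 + \beta_R R_i + \beta_U u_i + \beta_{RU} R_i u_i + \gamma_S S_i.}
#' `beta_RU` and `gamma_S` are platform options kept at zero in all core and
#' sensitivity grids.
#'
#' @param n Total randomised participants; must be a positive even integer
#'   (equal allocation to two arms).
#' @param family Outcome family, `"continuous"` or `"binary"`.
#' @param alpha_0 Intermediate-model intercept, log-odds scale. The default
#'   `log(0.2)` corresponds to a 17% control-arm event rate, a typical live
#'   birth rate in an unselected IVF population.
#' @param alpha_R Treatment effect on the intermediate, log odds ratio.
#' @param alpha_U Confounder effect on the intermediate, log odds ratio.
#'   The default `log(0.8)` makes higher prognostic index reduce the chance
#'   of the intermediate response.
#' @param alpha_RU Treatment-by-confounder interaction on the intermediate
#'   (log-OR scale); zero in "set 1" grids, `log(0.8)` in "set 2".
#' @param beta_0 Outcome intercept: control-group mean in grammes
#'   (continuous, default 3300) or control log-odds (binary, default
#'   `log(0.1)`, a 9% event rate).
#' @param beta_R Treatment effect on the outcome on the analysis scale:
#'   grammes (continuous) or log odds ratio (binary). This is the
#'   hypothetical estimand -- the effect that would apply were no truncation
#'   to occur -- against which analyses are scored.
#' @param beta_U Confounder effect on the outcome: grammes (continuous,
#'   default -116 = -0.2 SD) or log OR (binary, default `log(1.2)`).
#' @param sigma Residual SD of the continuous outcome in grammes (default
#'   580); ignored for binary outcomes.
#' @param beta_RU Optional treatment-by-confounder interaction on the
#'   outcome; default 0.
#' @param gamma_S Optional direct path from the intermediate to the outcome;
#'   default 0.
#' @param n_iterations Monte-Carlo repetitions when the scenario is run
#'   (default 10000).
#' @param seed Optional integer base seed attached to the scenario; may be
#'   overridden at run time.
#'
#' @return An object of class `scenario_params` (a named list).
#' @examples
#' p <- scenario_params(n = 500, family = "continuous", alpha_R = log(1.2),
#'                      beta_R = 0.2 * 580)
#' p
#' @export
scenario_params <- function(n,
                            family = c("continuous", "binary"),
                            alpha_0 = log(0.2),
                            alpha_R = 0,
                            alpha_U = log(0.8),
                            alpha_RU = 0,
                            beta_0 = NULL,
                            beta_R = 0,
                            beta_U = NULL,
                            sigma = 580,
                            beta_RU = 0,
                            gamma_S = 0,
                            n_iterations = 10000L,
                            seed = NULL) {
  family <- match.arg(family)
  if (is.null(beta_0)) beta_0 <- if (family == "continuous") 3300 else log(0.1)
  if (is.null(beta_U)) beta_U <- if (family == "continuous") -116 else log(1.2)
  p <- structure(
    list(
      n = n, family = family,
      alpha_0 = alpha_0, alpha_R = alpha_R, alpha_U = alpha_U,
      alpha_RU = alpha_RU,
      beta_0 = beta_0, beta_R = beta_R, beta_U = beta_U, sigma = sigma,
      beta_RU = beta_RU, gamma_S = gamma_S,
      n_iterations = as.integer(n_iterations),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "scenario_params"
  )
  validate_scenario_params(p)
}

#' Validate a `scenario_params` object
#'
#' Checks the scenario invariants: even positive `n` (equal allocation),
#' positive `sigma`, at least one iteration, finite coefficients, and a
#' recognised outcome family.
#'
#' @param p A [scenario_params()] object.
#' @return `p`, invisibly unchanged, or an error.
#' @export
validate_scenario_params <- function(p) {
  stopifnot(inherits(p, "scenario_params"))
  if (length(p$n) != 1 || !is.numeric(p$n) || is.na(p$n) ||
      p$n <= 0 || p$n != as.integer(p$n)) {
    abort("`n` must be a single positive integer.", class = "truncsim_invalid_parameter")
  }
  if (p$n %% 2 != 0) {
    abort("`n` must be even: participants are divided equally between two arms.",
          class = "truncsim_invalid_parameter")
  }
  if (!p$family %in% c("continuous", "binary")) {
    abort("`family` must be 'continuous' or 'binary'.",
          class = "truncsim_invalid_parameter")
  }
  num <- c("alpha_0", "alpha_R", "alpha_U", "alpha_RU",
           "beta_0", "beta_R", "beta_U", "beta_RU", "gamma_S")
  for (f in num) {
    v <- p[[f]]
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v)) {
      abort(paste0("`", f, "` must be a single finite number."),
            class = "truncsim_invalid_parameter")
    }
  }
  if (p$family == "continuous" &&
      (!is.numeric(p$sigma) || length(p$sigma) != 1 || !is.finite(p$sigma) ||
       p$sigma <= 0)) {
    abort("`sigma` must be a single positive number.",
          class = "truncsim_invalid_parameter")
  }
  if (p$n_iterations < 1) {
    abort("`n_iterations` must be at least 1.",
          class = "truncsim_invalid_parameter")
  }
  invisible(p)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>", x$family, "outcome, n =", x$n, "\n")
  cat(sprintf("  intermediate: logit(pi) = %.4g + %.4g R + %.4g u + %.4g R:u\n",
              x$alpha_0, x$alpha_R, x$alpha_U, x$alpha_RU))
  if (x$family == "continuous") {
    cat(sprintf("  outcome:      Y ~ N(%.4g + %.4g R + %.4g u, %.4g^2)\n",
                x$beta_0, x$beta_R, x$beta_U, x$sigma))
  } else {
    cat(sprintf("  outcome:      logit(p) = %.4g + %.4g R + %.4g u\n",
                x$beta_0, x$beta_R, x$beta_U))
  }
  if (x$beta_RU != 0 || x$gamma_S != 0) {
    cat(sprintf("  options:      beta_RU = %.4g, gamma_S = %.4g\n",
                x$beta_RU, x$gamma_S))
  }
  invisible(x)
}

#' Coerce a one-row data frame to `scenario_params`
#'
#' Used to run scenarios straight from the rows of a grid built by
#' [build_core_grid()] or [build_sensitivity_grid()]. Columns not naming a
#' scenario parameter (e.g. `suite`, `scenario_id`) are ignored.
#'
#' @param x A one-row data frame with scenario-parameter columns, or an
#'   existing `scenario_params` object (returned unchanged).
#' @return A [scenario_params()] object.
#' @export
as_scenario_params <- function(x) {
  if (inherits(x, "scenario_params")) return(x)
  stopifnot(is.data.frame(x), nrow(x) == 1)
  fields <- c("n", "family", "alpha_0", "alpha_R", "alpha_U", "alpha_RU",
              "beta_0", "beta_R", "beta_U", "sigma", "beta_RU", "gamma_S",
              "n_iterations", "seed")
  args <- as.list(x)[intersect(fields, names(x))]
  if (!is.null(args$sigma) && is.na(args$sigma)) args$sigma <- 580
  do.call(scenario_params, args)
}
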
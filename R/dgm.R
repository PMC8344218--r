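#' Deterministic equal allocation to two arms
#'
#' Returns the treatment indicator for a trial of `n` participants with
#' exactly `n/2` per arm: the first half treated, the second half control.
#' Allocation is deterministic rather than randomised because the confounder
#' is drawn i.i.d. independently of position, so the two orderings are
#' exchangeable.
#'
#' @param n Positive even integer.
#' @return Integer vector of length `n` with `n/2` ones then `n/2` zeros.
#' @examples
#' table(assign_treatment(100))
#' @export
assign_treatment <- function(n) {
  if (length(n) != 1 || !is.numeric(n) || is.na(n) || n <= 0 ||
      n != as.integer(n) || n %% 2 != 0) {
    abort("`n` must be a single positive even integer.",
          class = "truncsim_invalid_parameter")
  }
  rep(c(1L, 0L), each = n / 2)
}

#' Simulate the binary intermediate response
#'
#' Draws each participant's intermediate response (e.g. conception or live
#' birth) from a Bernoulli distribution with success probability
#' `plogis(alpha_0 + alpha_R * R + alpha_U * u + alpha_RU * R * u)`.
#' With `alpha_RU = 0` this is the plain additive model; a nonzero
#' interaction gives the "set 2" generating process.
#'
#' @param params A [scenario_params()] object.
#' @param R Treatment indicator vector (0/1).
#' @param u Confounder vector, same length as `R`.
#' @return Integer 0/1 vector of intermediate responses.
#' @export
simulate_intermediate <- function(params, R, u) {
  validate_scenario_params(params)
  if (length(R) != length(u)) {
    abort("`R` and `u` must have equal length.",
          class = "truncsim_invalid_parameter")
  }
  pi <- plogis(params$alpha_0 + params$alpha_R * R + params$alpha_U * u +
                 params$alpha_RU * R * u)
  rbinom(length(R), 1L, pi)
}

#' Simulate a continuous outcome for every participant
#'
#' Draws `Y_i ~ Normal(beta_0 + beta_R R_i + beta_U u_i + beta_RU R_i u_i +
#' gamma_S S_i, sigma^2)` for all participants, survivors and non-survivors
#' alike. Truncation is applied only at analysis time ([truncate_trial()]),
#' which keeps the hypothetical-estimand truth available in-sample.
#'
#' @inheritParams simulate_intermediate
#' @param S Intermediate-response vector (only used when `gamma_S != 0`).
#' @return Numeric outcome vector.
#' @export
simulate_continuous_outcome <- function(params, R, u, S) {
  validate_scenario_params(params)
  if (params$family != "continuous") {
    abort("`params$family` must be 'continuous' for a continuous outcome.",
          class = "truncsim_invalid_state")
  }
  mu <- params$beta_0 + params$beta_R * R + params$beta_U * u +
    params$beta_RU * R * u + params$gamma_S * S
  rnorm(length(R), mu, params$sigma)
}

#' Simulate a binary outcome for every participant
#'
#' Draws `Y_i ~ Bernoulli(plogis(beta_0 + beta_R R_i + beta_U u_i +
#' beta_RU R_i u_i + gamma_S S_i))` for all participants; truncation is
#' applied downstream.
#'
#' @inheritParams simulate_continuous_outcome
#' @return Integer 0/1 outcome vector.
#' @export
simulate_binary_outcome <- function(params, R, u, S) {
  validate_scenario_params(params)
  if (params$family != "binary") {
    abort("`params$family` must be 'binary' for a binary outcome.",
          class = "truncsim_invalid_state")
  }
  p <- plogis(params$beta_0 + params$beta_R * R + params$beta_U * u +
                params$beta_RU * R * u + params$gamma_S * S)
  rbinom(length(R), 1L, p)
}

# Internal fast path: plain list, no tibble construction. Uses the current
# RNG state; callers seed.
sim_trial_core <- function(params) {
  n <- params$n
  R <- rep(c(1L, 0L), each = n / 2)
  u <- rnorm(n)
  pi <- plogis(params$alpha_0 + params$alpha_R * R + params$alpha_U * u +
                 params$alpha_RU * R * u)
  S <- rbinom(n, 1L, pi)
  if (params$family == "continuous") {
    mu <- params$beta_0 + params$beta_R * R + params$beta_U * u +
      params$beta_RU * R * u + params$gamma_S * S
    Y <- rnorm(n, mu, params$sigma)
  } else {
    p <- plogis(params$beta_0 + params$beta_R * R + params$beta_U * u +
                  params$beta_RU * R * u + params$gamma_S * S)
    Y <- rbinom(n, 1L, p)
  }
  list(R = R, u = u, S = S, Y = Y)
}

#' Simulate one complete trial
#'
#' Composes the generators: equal deterministic allocation, a standard-normal
#' confounder `u`, the logistic intermediate response `S`, and the outcome
#' `Y` generated for every participant (truncation happens at analysis).
#' With a fixed seed the result is bit-identical across calls.
#'
#' @param params A [scenario_params()] object.
#' @param seed Optional integer; when supplied, the RNG is seeded before
#'   generation so the trial is reproducible in isolation.
#' @return A tibble with one row per participant and columns `R`, `u`, `S`,
#'   `Y`.
#' @examples
#' p <- scenario_params(n = 100, family = "continuous", alpha_R = log(1.2))
#' trial <- simulate_trial(p, seed = 1)
#' head(trial)
#' @export
simulate_trial <- function(params, seed = NULL) {
  validate_scenario_params(params)
  if (!is.null(seed)) set.seed(seed)
  tibble::as_tibble(sim_trial_core(params))
}
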
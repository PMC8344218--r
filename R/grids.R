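# The named scenario grids: core sets 1-2 for continuous and binary
# outcomes, and sensitivity variants A (stronger confounding), B (reversed
# treatment effect on the intermediate) and C (elevated event rates).

or_grid <- function() c(seq(1, 2, by = 0.05), 5)
sd_grid <- function() c(seq(0, 2, by = 0.1), 5)

# Deterministic 31-bit content hash of a string; used for scenario ids and
# per-scenario seed derivation so scenarios are reproducible independently
# and in parallel.
hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

scenario_id_of <- function(row) {
  key <- paste(row$family, row$n,
               sprintf("%.10g", c(row$alpha_0, row$alpha_R, row$alpha_U,
                                  row$alpha_RU, row$beta_0, row$beta_R,
                                  row$beta_U, row$sigma)),
               collapse = "|")
  sprintf("s%010d", hash31(key))
}

grid_tibble <- function(suite, set_id, family, alpha_0, alpha_R_or,
                        alpha_U, alpha_RU, beta_0, beta_R, beta_U, sigma) {
  g <- tidyr::expand_grid(
    n = c(100L, 200L, 500L, 1000L),
    alpha_R = log(alpha_R_or),
    beta_R = beta_R
  )
  sigma_col <- if (family == "continuous") sigma else NA_real_
  g <- dplyr::mutate(
    g,
    suite = suite, set_id = set_id, family = family,
    alpha_0 = alpha_0, alpha_U = alpha_U, alpha_RU = alpha_RU,
    beta_0 = beta_0, beta_U = beta_U,
    sigma = sigma_col,
    beta_RU = 0, gamma_S = 0
  )
  g <- dplyr::relocate(g, "suite", "set_id", "family")
  g$scenario_id <- purrr::map_chr(seq_len(nrow(g)),
                                  function(i) scenario_id_of(g[i, ]))
  stopifnot(!anyDuplicated(g$scenario_id))
  structure(dplyr::relocate(g, "scenario_id"), class = c("trunc_grid", class(g)))
}

#' Build a core scenario grid
#'
#' The cross-product of total sample size `n` in \{100, 200, 500, 1000\},
#' treatment effect on the intermediate `exp(alpha_R)` in
#' \{1.00, 1.05, ..., 2.00, 5\} (22 values), and treatment effect on the
#' outcome: `beta_R` in \{0, 0.1, ..., 2, 5\} SDs converted to grammes
#' (continuous) or `exp(beta_R)` in \{1.00, 1.05, ..., 2.00, 5\} (binary) --
#' 1936 scenarios per set and family. Fixed parameters: intermediate
#' intercept `log(0.2)` (17% control event rate), confounder effect
#' `log(0.8)` on the intermediate and -0.2 SD / `log(1.2)` on the outcome,
#' outcome intercept 3300 g / `log(0.1)`, residual SD 580 g. Set 2 differs
#' from set 1 only by the treatment-by-confounder interaction on the
#' intermediate, `alpha_RU = log(0.8)`.
#'
#' @param set_id 1 (no interaction) or 2 (interaction on the intermediate).
#' @param family `"continuous"` or `"binary"`.
#' @return A `trunc_grid` tibble, one row per scenario, with a content-hash
#'   `scenario_id` column.
#' @examples
#' nrow(build_core_grid(1, "continuous"))
#' @export
build_core_grid <- function(set_id = 1, family = c("continuous", "binary")) {
  family <- match.arg(family)
  if (!set_id %in% c(1, 2)) {
    abort("`set_id` must be 1 or 2.", class = "truncsim_invalid_parameter")
  }
  sigma <- 580
  grid_tibble(
    suite = sprintf("core-set%d-%s", set_id, family),
    set_id = as.integer(set_id), family = family,
    alpha_0 = log(0.2), alpha_R_or = or_grid(), alpha_U = log(0.8),
    alpha_RU = if (set_id == 2) log(0.8) else 0,
    beta_0 = if (family == "continuous") 3300 else log(0.1),
    beta_R = if (family == "continuous") sd_grid() * sigma else log(or_grid()),
    beta_U = if (family == "continuous") -0.2 * sigma else log(1.2),
    sigma = sigma
  )
}

#' Build a sensitivity-analysis scenario grid
#'
#' Applies one uniform modification to the corresponding core grid:
#' * **A** -- stronger confounding: `alpha_U = log(0.5)`, and `beta_U = -1`
#'   SD (continuous) or `log(1.5)` (binary);
#' * **B** -- reversed treatment effect on the intermediate: the
#'   `exp(alpha_R)` grid becomes the reciprocals \{1, 1/1.05, ..., 1/2,
#'   1/5\}, checking that opposing influences were not cancelling;
#' * **C** -- elevated event rates: the intermediate intercept (and, for
#'   binary outcomes, the outcome intercept) is set to 0, a 50% event rate,
#'   which largely removes separation-driven missingness.
#'
#' @param which `"A"`, `"B"` or `"C"`.
#' @inheritParams build_core_grid
#' @return A `trunc_grid` tibble.
#' @export
build_sensitivity_grid <- function(which = c("A", "B", "C"), set_id = 1,
                                   family = c("continuous", "binary")) {
  which <- match.arg(which)
  family <- match.arg(family)
  if (!set_id %in% c(1, 2)) {
    abort("`set_id` must be 1 or 2.", class = "truncsim_invalid_parameter")
  }
  sigma <- 580
  alpha_U <- if (which == "A") log(0.5) else log(0.8)
  beta_U <- if (which == "A") {
    if (family == "continuous") -1 * sigma else log(1.5)
  } else {
    if (family == "continuous") -0.2 * sigma else log(1.2)
  }
  alpha_R_or <- if (which == "B") 1 / or_grid() else or_grid()
  alpha_0 <- if (which == "C") 0 else log(0.2)
  beta_0 <- if (family == "continuous") {
    3300
  } else if (which == "C") 0 else log(0.1)
  grid_tibble(
    suite = sprintf("sens%s-set%d-%s", which, set_id, family),
    set_id = as.integer(set_id), family = family,
    alpha_0 = alpha_0, alpha_R_or = alpha_R_or, alpha_U = alpha_U,
    alpha_RU = if (set_id == 2) log(0.8) else 0,
    beta_0 = beta_0,
    beta_R = if (family == "continuous") sd_grid() * sigma else log(or_grid()),
    beta_U = beta_U, sigma = sigma
  )
}

#' List the named scenario suites
#'
#' @return A tibble with columns `suite`, `set_id`, `family`, `sensitivity`.
#' @export
list_suites <- function() {
  tidyr::expand_grid(
    sensitivity = c("core", "A", "B", "C"),
    set_id = 1:2,
    family = c("continuous", "binary")
  ) |>
    dplyr::mutate(
      suite = ifelse(.data$sensitivity == "core",
                     sprintf("core-set%d-%s", .data$set_id, .data$family),
                     sprintf("sens%s-set%d-%s", .data$sensitivity,
                             .data$set_id, .data$family))
    ) |>
    dplyr::relocate("suite")
}

#' Materialise a suite grid by name
#'
#' @param suite A suite name as listed by [list_suites()], e.g.
#'   `"core-set1-continuous"` or `"sensA-set2-binary"`.
#' @return A `trunc_grid` tibble.
#' @export
suite_grid <- function(suite) {
  m <- regmatches(suite,
                  regexec("^(core|sens([ABC]))-set([12])-(continuous|binary)$", suite))[[1]]
  if (length(m) == 0) {
    abort(paste0("Unknown suite '", suite, "'; see list_suites()."),
          class = "truncsim_invalid_parameter")
  }
  set_id <- as.integer(m[4])
  family <- m[5]
  if (m[2] == "core") build_core_grid(set_id, family)
  else build_sensitivity_grid(m[3], set_id, family)
}
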
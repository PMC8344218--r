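# Scenario and suite runners. Each scenario gets its own RNG substream,
# derived deterministically from the base seed and the scenario's content
# hash, so results do not depend on execution order or on which other
# scenarios ran.

#' Derive a per-scenario seed from a base seed and scenario id
#'
#' Combines a base integer seed with the 31-bit content hash of the
#' scenario id: `(hash(id) + base_seed) mod (2^31 - 1)`. The scheme is
#' platform-stable and keeps every derived seed a valid 32-bit integer, so
#' any scenario can be re-run in isolation.
#'
#' @param base_seed Integer base seed for the run.
#' @param scenario_id Scenario identifier string.
#' @return A single integer seed.
#' @export
derive_seed <- function(base_seed, scenario_id) {
  as.integer((hash31(as.character(scenario_id)) + as.numeric(base_seed)) %% 2147483647)
}

#' Run one scenario
#'
#' Repeats `simulate_trial` then `analyse_trial` for `n_iterations`
#' Monte-Carlo repetitions and aggregates the per-iteration results with
#' [summarise_scenario()]. Deterministic given `(seed, params)`. Numerical
#' failures in a single iteration are caught, logged and recorded as
#' incomputable rather than aborting the run.
#'
#' @param params A [scenario_params()] object or a one-row grid data frame.
#' @param n_iterations Number of repetitions; defaults to
#'   `params$n_iterations`.
#' @param seed Integer seed for this scenario; defaults to `params$seed`,
#'   else 1.
#' @param compute_ci Compute the profile-likelihood interval per iteration
#'   (binary only; default `TRUE`). Disable when only point-estimate
#'   measures are needed -- the profile solve dominates binary runtime.
#' @param compute_tests Compute the three 2x2 tests per iteration (binary
#'   only; default `TRUE`).
#' @param keep_records Keep the per-iteration records tibble in the result
#'   (default `FALSE`).
#' @param alpha,denominator,se_method,ror_method Passed to
#'   [summarise_scenario()].
#' @return An object of class `trunc_performance`: a list with elements
#'   `params`, `seed`, `summary` (one-row tibble) and `records` (tibble or
#'   `NULL`). Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' p <- scenario_params(n = 100, family = "continuous", alpha_R = log(1.2),
#'                      n_iterations = 50)
#' glance(run_scenario(p, seed = 1))
#' @export
run_scenario <- function(params, n_iterations = NULL, seed = NULL,
                         compute_ci = TRUE, compute_tests = TRUE,
                         keep_records = FALSE, alpha = 0.05,
                         denominator = c("computable", "all"),
                         se_method = c("rms", "mean"),
                         ror_method = c("mean_or", "geometric")) {
  if (is.data.frame(params)) params <- as_scenario_params(params)
  validate_scenario_params(params)
  denominator <- match.arg(denominator)
  se_method <- match.arg(se_method)
  m <- if (is.null(n_iterations)) params$n_iterations else as.integer(n_iterations)
  if (m < 1) abort("`n_iterations` must be at least 1.",
                   class = "truncsim_invalid_parameter")
  seed <- if (!is.null(seed)) as.integer(seed) else if (!is.null(params$seed)) params$seed else 1L
  set.seed(seed)

  continuous <- params$family == "continuous"
  rows <- vector("list", m)
  n_failed <- 0L
  for (it in seq_len(m)) {
    trial <- sim_trial_core(params)
    rows[[it]] <- tryCatch(
      if (continuous) {
        arms <- list(y_treat = trial$Y[trial$S == 1L & trial$R == 1L],
                     y_ctrl  = trial$Y[trial$S == 1L & trial$R == 0L])
        diff_means_core(arms$y_treat, arms$y_ctrl)
      } else {
        keep <- trial$S == 1L
        R <- trial$R[keep]; Y <- trial$Y[keep]
        tab <- c(sum(R & Y), sum(R & !Y), sum(!R & Y), sum(!R & !Y))
        analyse_binary_core(tab, compute_ci = compute_ci,
                            compute_tests = compute_tests)
      },
      error = function(e) {
        n_failed <<- n_failed + 1L
        NULL
      }
    )
  }
  if (n_failed > 0) {
    warn(sprintf("%d of %d iterations failed numerically and were recorded as incomputable.",
                 n_failed, m))
    # replace failures with fully-missing records of the right layout
    blank <- if (continuous) {
      diff_means_core(numeric(0), numeric(0))
    } else {
      analyse_binary_core(c(0, 1, 0, 1), compute_ci = FALSE, compute_tests = FALSE)
    }
    blank[] <- lapply(blank, function(x) x[NA])
    rows[vapply(rows, is.null, logical(1))] <- list(blank)
  }
  records <- dplyr::bind_rows(lapply(rows, tibble::new_tibble, nrow = 1L))
  summary <- summarise_scenario(records, params, alpha = alpha,
                                denominator = denominator,
                                se_method = se_method,
                                ror_method = match.arg(ror_method))
  structure(
    list(params = params, seed = seed, n_iterations = m,
         summary = summary,
         records = if (keep_records) records else NULL),
    class = "trunc_performance"
  )
}

#' Run every scenario in a grid
#'
#' Maps [run_scenario()] over the rows of a grid built by
#' [build_core_grid()], [build_sensitivity_grid()] or [suite_grid()]. Each
#' scenario's seed is derived from `seed` and its `scenario_id` via
#' [derive_seed()], so the output is invariant to execution order and a
#' subset of scenarios can be reproduced in isolation. When
#' `checkpoint_dir` is given, each finished scenario's summary row is
#' written to `<checkpoint_dir>/<scenario_id>.csv` and an interrupted suite
#' resumes without re-running completed scenarios.
#'
#' @param grid A scenario grid tibble (one row per scenario, including a
#'   `scenario_id` column).
#' @param n_iterations Monte-Carlo repetitions per scenario (default 10000).
#' @param seed Integer base seed for the suite.
#' @param checkpoint_dir Optional directory for per-scenario checkpoints.
#' @param progress Print one line per scenario (default `FALSE`).
#' @param ... Passed on to [run_scenario()] (e.g. `compute_ci`,
#'   `denominator`).
#' @return A tibble of class `trunc_suite`: the grid columns joined to one
#'   summary row per scenario.
#' @examples
#' g <- build_core_grid(1, "continuous")[c(1, 30), ]
#' run_suite(g, n_iterations = 20, seed = 1)
#' @export
run_suite <- function(grid, n_iterations = 10000L, seed = 1L,
                      checkpoint_dir = NULL, progress = FALSE, ...) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0) {
    return(structure(tibble::tibble(), class = c("trunc_suite", class(tibble::tibble()))))
  }
  stopifnot("scenario_id" %in% names(grid))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  run_one <- function(i) {
    id <- grid$scenario_id[i]
    cp <- if (!is.null(checkpoint_dir)) file.path(checkpoint_dir, paste0(id, ".csv"))
    if (!is.null(cp) && file.exists(cp)) {
      return(readr::read_csv(cp, show_col_types = FALSE))
    }
    res <- run_scenario(grid[i, ], n_iterations = n_iterations,
                        seed = derive_seed(seed, id), ...)
    row <- dplyr::bind_cols(
      tibble::as_tibble(grid[i, ]),
      dplyr::rename_with(res$summary, ~paste0("perf_", .x),
                         dplyr::any_of("family"))
    )
    if (progress) {
      message(sprintf("[%d/%d] %s done", i, nrow(grid), id))
    }
    if (!is.null(cp)) readr::write_csv(row, cp)
    row
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), run_one))
  structure(out, class = c("trunc_suite", setdiff(class(out), "trunc_suite")))
}
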
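#' @export
print.trunc_performance <- function(x, ...) {
  p <- x$params
  cat(sprintf("<trunc_performance> %s outcome, n = %d, %d iterations (seed %d)\n",
              p$family, p$n, x$n_iterations, x$seed))
  s <- x$summary
  cat(sprintf("  estimable %d / separated or incomputable %d\n",
              s$n_estimable, s$n_separated))
  if (p$family == "continuous") {
    cat(sprintf("  bias %.3f g (%.4f SD), emp SE %.2f, model SE %.2f, coverage %.3f, t rejection %.3f\n",
                s$bias, s$bias_sd_units, s$empirical_se, s$model_se,
                s$coverage, s$rej_t))
  } else {
    cat(sprintf("  bias(logOR) %.4f, ROR %.3f, emp SE %.3f, model SE %.3f, coverage %.3f\n",
                s$bias, s$ror, s$empirical_se, s$model_se, s$coverage))
    cat(sprintf("  rejection: chi2 %.3f, 'N-1' chi2 %.3f, Fisher %.3f\n",
                s$rej_chi2, s$rej_chi2_adj, s$rej_fisher))
  }
  invisible(x)
}

#' Tidy a scenario's performance summary into long form
#'
#' One row per performance measure, with its Monte-Carlo standard error
#' where one is defined.
#'
#' @param x A `trunc_performance` object from [run_scenario()].
#' @param ... Unused.
#' @return A tibble with columns `measure`, `value`, `mc_se`.
#' @method tidy trunc_performance
#' @export
tidy.trunc_performance <- function(x, ...) {
  s <- x$summary
  measures <- c("bias", "bias_sd_units", "ror", "empirical_se", "model_se",
                "coverage", "rej_t", "rej_chi2", "rej_chi2_adj", "rej_fisher")
  rows <- purrr::map(measures, function(m) {
    v <- s[[m]]
    if (is.null(v) || is.na(v)) return(NULL)
    se_col <- paste0(m, "_mc_se")
    tibble::tibble(measure = m, value = v,
                   mc_se = if (se_col %in% names(s)) s[[se_col]] else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a scenario run
#'
#' @param x A `trunc_performance` object from [run_scenario()].
#' @param ... Unused.
#' @return The one-row wide summary tibble, with the scenario's key
#'   parameters prepended.
#' @method glance trunc_performance
#' @export
glance.trunc_performance <- function(x, ...) {
  p <- x$params
  dplyr::bind_cols(
    tibble::tibble(n = p$n, alpha_R = p$alpha_R, beta_R = p$beta_R,
                   seed = x$seed),
    dplyr::select(x$summary, -"family")
  )
}
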
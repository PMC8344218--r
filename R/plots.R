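# Visualisation of suite summaries: a chosen performance measure against
# the intermediate-effect odds ratio exp(alpha_R), faceted by sample size,
# one series per treatment effect on the outcome.

measure_columns <- function() {
  c("bias", "bias_sd_units", "ror", "empirical_se", "model_se", "coverage",
    "rej_t", "rej_chi2", "rej_chi2_adj", "rej_fisher")
}

#' Plot a performance measure across a suite summary
#'
#' Line plot of `measure` against the treatment effect on the intermediate
#' (`exp(alpha_R)`), faceted by total sample size `n`, coloured by the
#' treatment effect on the outcome.
#'
#' @param summary A suite summary tibble from [run_suite()] (or one read
#'   back from its CSV).
#' @param measure One of `bias`, `bias_sd_units`, `ror`, `empirical_se`,
#'   `model_se`, `coverage`, `rej_t`, `rej_chi2`, `rej_chi2_adj`,
#'   `rej_fisher`.
#' @return A ggplot object.
#' @export
plot_measure <- function(summary, measure = "bias") {
  stopifnot(is.data.frame(summary))
  if (nrow(summary) == 0) {
    warn("Empty summary: nothing to plot.")
    return(invisible(NULL))
  }
  if (!measure %in% measure_columns() || !measure %in% names(summary)) {
    abort(paste0("Unknown or absent measure '", measure, "'."),
          class = "truncsim_invalid_parameter")
  }
  df <- dplyr::mutate(summary,
                      or_intermediate = exp(.data$alpha_R),
                      outcome_effect = factor(signif(.data$beta_R, 4)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_intermediate,
                                   y = .data[[measure]],
                                   colour = .data$outcome_effect,
                                   group = .data$outcome_effect)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$n), nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Treatment effect on intermediate (odds ratio)",
                  y = measure, colour = "Effect on outcome") +
    ggplot2::theme_bw()
}

#' @rdname plot_measure
#' @param object A `trunc_suite` tibble from [run_suite()].
#' @param ... Unused.
#' @method autoplot trunc_suite
#' @export
autoplot.trunc_suite <- function(object, measure = "bias", ...) {
  plot_measure(object, measure = measure)
}
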
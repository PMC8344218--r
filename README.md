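# truncsim

Simulation platform for **outcome truncation** in two-arm randomised trials.

In reproductive medicine RCTs, many outcomes are only defined for the subset
of participants who experience a binary intermediate response: birthweight
exists only for participants who give birth, miscarriage only for those who
conceive. These truncated outcomes are routinely analysed by comparing arms
within the uncensored subgroup — but when treatment changes the probability
of the intermediate response, that comparison is no longer randomised, and
conditioning on the intermediate opens a selection (collider) path through
unmeasured prognostic factors. `truncsim` lets trialists and methodologists
quantify what this does to the standard analyses, under parameter settings
they control.

## The model

Each simulated trial has `n` participants split equally between arms
(`R = 1` treatment, `R = 0` control), a standard-normal unmeasured
confounder `u`, an intermediate response

    logit Pr(S = 1) = α₀ + α_R R + α_U u + α_RU R·u

and a study outcome generated for **everyone** (truncation happens only at
analysis, by discarding `S = 0` rows):

    continuous:  Y ~ Normal(β₀ + β_R R + β_U u, σ²)
    binary:      logit Pr(Y = 1) = β₀ + β_R R + β_U u

Bias arises whenever `α_R`, `α_U` and `β_U` are all nonzero. Estimates are
scored against the **hypothetical estimand** `β_R` — the treatment effect
that would apply were no truncation to occur.

The analyses applied to the survivor subgroup are the ones the field
actually uses:

* continuous — difference in means, pooled-variance (equal-variance)
  two-sample t-test and t-based 95% CI;
* binary — sample odds ratio (the logistic-regression MLE) with Wald SE and
  a profile-likelihood 95% CI, plus the Pearson chi-squared test (no
  continuity correction), the small-sample **'N−1' chi-squared** variant
  (Pearson × (N−1)/N), and Fisher's exact test.

Separated 2×2 tables (none or all events in an arm) leave the OR
inestimable; the platform flags them and reports them as missing data, which
is itself one of the study's main findings for small trials.

Performance per scenario: bias (SD units for continuous outcomes; ratio of
estimated to true odds ratio, ROR, for binary), empirical and model SE,
CI coverage, and per-test rejection rates, each with a Monte-Carlo standard
error and explicit accounting of separated / incomputable iterations.

## Worked example

A realistic binary scenario: OR 1.2 of treatment on the intermediate
response (about the largest effect typical of infertility trials), OR 1.2 on
the outcome, 500 participants:

```r
library(truncsim)

p <- scenario_params(n = 500, family = "binary",
                     alpha_R = log(1.2), beta_R = log(1.2))
res <- run_scenario(p, n_iterations = 2000, seed = 2024)
res
#> <trunc_performance> binary outcome, n = 500, 2000 iterations (seed 2024)
#>   estimable 1941 / separated or incomputable 59
#>   bias(logOR) -0.0004, ROR 1.327, emp SE 0.749, model SE 0.798, coverage 0.972
#>   rejection: chi2 0.045, 'N-1' chi2 0.043, Fisher 0.028
tidy(res)
#> # A tibble: 8 × 3
#>   measure          value    mc_se
#>   <chr>            <dbl>    <dbl>
#> 1 bias         -0.000369  0.0170
#> 2 ror           1.33      0.0258
#> 3 empirical_se  0.749     0.0120
#> 4 model_se      0.798    NA
#> 5 coverage      0.972     0.00373
#> 6 rej_chi2      0.045     0.00464
#> 7 rej_chi2_adj  0.0435    0.00456
#> 8 rej_fisher    0.028     0.00369
```

Reading this: the mean log-OR bias is negligible (−0.0004 ± 0.017), but
3% of iterations are already separated at n = 500 with a ~9% event rate, the
mean of the estimated ORs overshoots the truth by ~33% (the OR's sampling
distribution is right-skewed at these event counts), coverage is above
nominal (the model SE exceeds the empirical SE of the computable estimates),
and Fisher's test rejects well below the 5% level.

Full study grids are available by name and run the same way:

```r
g <- suite_grid("core-set1-binary")        # 1936 scenarios
s <- run_suite(g[1:4, ], n_iterations = 1000, seed = 1)
autoplot(s, measure = "ror")
```

A thin command-line runner wraps the same functions:

```sh
Rscript inst/cli/truncsim.R run --suite core-set1-continuous \
    --iterations 1000 --seed 7 --output-dir out
Rscript inst/cli/truncsim.R list-suites
```

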
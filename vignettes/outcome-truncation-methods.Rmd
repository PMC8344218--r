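---
title: "Methods: simulating and analysing truncated trial outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing truncated trial outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data-generating model

`truncsim` studies two-arm randomised trials in which a binary
post-randomisation event — conception, live birth — determines whether the
study outcome exists at all. Outcome truncation is not ordinary missingness:
a birthweight for a participant who did not give birth is undefined, not
unobserved. The field's standard response is to compare arms within the
uncensored subgroup, and the purpose of this package is to measure what that
costs.

Each simulated trial draws, per participant *i*:

* a treatment indicator $R_i$, with exactly $n/2$ per arm;
* an unmeasured prognostic index $u_i \sim N(0, 1)$;
* an intermediate response
  $S_i \sim \text{Bern}(\pi_i)$,
  $\operatorname{logit} \pi_i = \alpha_0 + \alpha_R R_i + \alpha_U u_i +
  \alpha_{RU} R_i u_i$;
* an outcome for **every** participant:
  $Y_i \sim N(\mu_i, \sigma^2)$ with
  $\mu_i = \beta_0 + \beta_R R_i + \beta_U u_i$ (continuous), or
  $Y_i \sim \text{Bern}(p_i)$ with
  $\operatorname{logit} p_i = \beta_0 + \beta_R R_i + \beta_U u_i$ (binary).

Truncation is applied only at analysis time by discarding $S_i = 0$ rows.
Generating $Y$ for everyone makes the estimand truth available in-sample for
diagnostics and is statistically identical to generating outcomes for
survivors only, because the analysis never touches non-survivor outcomes.

Because $u$ enters both submodels, conditioning on $S = 1$ links $R$ to $u$
among survivors, and through $\beta_U$ to the outcome: selection (collider)
bias, which requires $\alpha_R$, $\alpha_U$ and $\beta_U$ all nonzero. With
$\alpha_R = 0$, selection is equally strong in both arms and the survivor
contrast remains unbiased — a property the test suite checks directly.

Two structural options are carried by the generator but held at zero in all
shipped grids: a treatment-by-confounder interaction on the outcome
($\beta_{RU}$) and a direct path from the intermediate to the outcome
($\gamma_S$). They are deliberate extension points, not study conditions.

**Allocation is deterministic** (first $n/2$ rows treated). Randomising the
allocation would only permute i.i.d. draws of $u$; omitting it removes a
source of noise without changing any distribution.

## Default parameter values and what they emulate

The defaults describe a typical assisted-reproduction trial:

| parameter | default | meaning |
|---|---|---|
| $\alpha_0$ | $\log 0.2$ | ~17% control-arm live-birth/conception rate |
| $\alpha_U$ | $\log 0.8$ | higher prognostic index → less likely to be observed |
| $\beta_0$ | 3300 g / $\log 0.1$ | control birthweight mean / ~9% event rate |
| $\beta_U$ | −116 g (−0.2 SD) / $\log 1.2$ | confounder's effect on the outcome |
| $\sigma$ | 580 g | residual SD of birthweight |

The grids vary $n \in \{100, 200, 500, 1000\}$, the intermediate effect
$e^{\alpha_R} \in \{1.00, 1.05, \ldots, 2.00, 5\}$ and the outcome effect
($\beta_R$ in 0–2 SDs plus 5, or the same OR ladder), giving 1936 scenarios
per set and family. Effects above OR ≈ 1.2 on the intermediate are already
exceptional for infertility interventions; the 2 and 5 settings exist to
bound the phenomenon, not to represent plausible trials. "Set 2" adds
$\alpha_{RU} = \log 0.8$; sensitivity suite A strengthens confounding
($\alpha_U = \log 0.5$, $\beta_U = -1$ SD or $\log 1.5$), B reverses the
intermediate effect, C raises the event rates.

Two sensitivity settings required an interpretation, fixed once here:

* **Suite B** uses reciprocal odds ratios,
  $e^{\alpha_R} \in \{1, 1/1.05, \ldots, 1/2, 1/5\}$: the point of the suite
  is to reverse the *direction* of the treatment effect on the intermediate,
  and a sign flip of the log-OR ladder is the only reading that does that.
* **Suite C** sets the intermediate intercept — and for binary outcomes the
  outcome intercept — to $0 = \log 1$, which is exactly a 50% event rate.
  The continuous outcome intercept (a mean in grammes) is untouched.

What the generator does **not** emulate: covariates you could adjust for,
non-normal confounding, informative loss to follow-up distinct from
truncation, repeated treatment cycles, and any causal path $S \to Y$ under
the default $\gamma_S = 0$. Passing tests therefore show that the analysis
machinery behaves as designed under this stylised world; they do not certify
behaviour under, say, heavy-tailed birthweight distributions.

## Analysis methods

All analyses act on the survivor subgroup only.

**Continuous.** Difference in survivor means, pooled-variance SE, two-sided
equal-variance t-test, t-based 95% CI. The analysis is *incomputable* when
either arm has fewer than two survivors (the pooled variance is undefined);
such iterations are counted as missing. In practice this is rare — it takes
$n = 100$ with a very harmful intermediate effect to see it at all.

**Binary.** The survivor 2×2 table (treated events $a$, non-events $b$;
control $c$, $d$) yields:

* the sample log OR $\log(ad/bc)$ — identical to the MLE of the treatment
  coefficient in a logistic regression on treatment alone, a closed form the
  test suite verifies against an iterative fit — with Wald SE
  $\sqrt{1/a + 1/b + 1/c + 1/d}$;
* a **profile-likelihood 95% CI**: the two values of the log OR where twice
  the drop from the maximised binomial log-likelihood, profiling out the
  intercept, equals $\chi^2_1(0.95)$. Numerics: the intercept is profiled by
  Newton iteration on the score (converges in a handful of steps for any
  non-separated table); each endpoint is bracketed between the MLE and the
  MLE ± 10 Wald SEs (widened, then reported as a numerical error with
  diagnostics, if ever insufficient) and bisected until the deviance
  condition holds to 1e−8. Endpoints are validated in the tests against an
  independent `optimize`-based profile and against `MASS::confint` on the
  logistic fit;
* three tests: Pearson chi-squared **without** continuity correction, the
  'N−1' variant (Pearson × $(N-1)/N$, $N$ = survivor total — defined
  relative to the *uncorrected* statistic, otherwise the scaling relation
  that defines it is lost), and Fisher's exact test under the
  probability-mass two-sided convention (tables at most as probable as the
  observed one; conventions differ across software, so this is stated).

**Degeneracy rules.** A table is *separated* when any cell is zero — none or
all events in an arm, including empty arms — exactly the condition under
which the log OR and Wald SE are undefined. The chi-squared tests are
incomputable when a row or column margin is zero (an expected count of
zero); a zero *cell* with positive margins is fine. The margin rule is a
choice (a zero-cell rule would also be defensible): it is the weakest rule
that keeps the statistic well-defined, and it is exposed rather than buried —
separated and incomputable iterations are tallied per test in every summary.
Fisher's test is always computable; with a zero column margin only one table
is consistent with the margins and $p = 1$.

## Performance measures

Against the hypothetical estimand $\beta_R$ (grammes or log OR):

* **bias** = mean(estimate) − truth, over estimable iterations; continuous
  bias also in SD units (÷ 580);
* **ROR** (binary) = ratio of estimated to true odds ratio. The default is
  $\overline{\widehat{OR}} / OR_{true}$ — the arithmetic mean of the
  estimated odds ratios over the true one. An alternative convention
  exponentiates the mean log-OR bias (the geometric-mean ratio); both are
  implemented (`ror(..., method =)`). They diverge exactly when the OR's
  sampling distribution is right-skewed, i.e. in small survivor subgroups
  with few events, where the arithmetic convention can sit far above 1 while
  the log-scale bias is modest. The arithmetic convention is the default
  because it is the quantity a reader of a forest plot of ORs implicitly
  averages, and it is the scale on which the small-sample inflation at
  extreme intermediate effects (ROR ≈ 1.35 at $n = 500$) is visible at all;
* **empirical SE** = sample SD of estimable estimates; **model SE** =
  root-mean-square of the per-iteration model SEs (RMS makes it an estimate
  of the same variance the empirical SE estimates; an arithmetic mean is
  available). Their gap diagnoses SE calibration — under informative
  missingness the model SE exceeds the empirical SE of the *computable*
  estimates, which is what pushes small-trial coverage above nominal;
* **coverage** = proportion of computable intervals containing the truth;
* **rejection rates** per test, with two denominator conventions:
  `"computable"` (default; incomputable statistics excluded) and `"all"`
  (incomputable counted as non-rejections). The conventions answer different
  questions — "how does the test behave when it runs?" versus "how often
  does this trial design produce a rejection?" — and the second is the one
  under which small-trial type-1 error falls below nominal, because
  one-fifth of small-trial iterations never produce a statistic.

Every measure carries a Monte-Carlo SE (binomial for proportions,
$\widehat{SE}_{emp}/\sqrt{m}$ for bias, delta-method for the ROR), so
reduced-replication runs can state tolerance bands; conservation
$n_{estimable} + n_{separated} = n_{iterations}$ is asserted in the tests.

## Reproducibility

One base seed governs a run. Each scenario derives its own seed as
$(\text{hash}_{31}(\text{scenario id}) + \text{base}) \bmod (2^{31}-1)$,
where the scenario id is itself a 31-bit content hash of the parameter
values. Consequences, all tested: suite output is invariant to execution
order; any single scenario can be re-run in isolation bit-identically;
checkpointed suites resume without recomputation; and a scenario's identity
(hence seed) changes if and only if its parameters do. All derived seeds
stay below $2^{31}$, the range of R's integer seeds.

## Problem sizes

The shipped grids default to 10,000 iterations per scenario, and the
package's own acceptance checks run their quantitative claims at that full
replication (each such scenario takes a few seconds). The broader test suite
exercises the machinery at 20–3000 iterations — enough that every assertion
sits several Monte-Carlo SEs clear of its threshold, with the MC SEs
reported by the summaries themselves used to size the margins. Calibration
checks of marginal event rates use $10^6$ participants ($\pm 0.04$% at a 17%
rate).

## Known limitations

* The unadjusted analyses studied here are the field's practice, not its
  best option; covariate adjustment, Firth-penalised logistic regression and
  weighting approaches are out of scope by design.
* The binary truth is the conditional coefficient $\beta_R$;
  non-collapsibility of the odds ratio contributes a small positive large-n
  component to the measured bias that is a property of the estimand choice,
  not of truncation.
* Fisher's test is evaluated against margins that vary across iterations
  (survivor counts are random), which is precisely why its rejection rate is
  persistently conservative here; this is a finding, not a defect, but it
  means the Fisher results should not be read as a general indictment of the
  test under fixed margins.
* A single shared confounder is a modelling convenience; separate partially
  correlated confounders for the two submodels would interpolate between
  the $\alpha_U \beta_U \neq 0$ and independent cases and are not
  implemented.
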
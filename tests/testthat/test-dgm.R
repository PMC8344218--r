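test_that("scenario parameter validation enforces the design invariants", {
  expect_s3_class(scenario_params(n = 100, family = "continuous"),
                  "scenario_params")
  expect_error(scenario_params(n = 3, family = "continuous"),
               class = "truncsim_invalid_parameter")
  expect_error(scenario_params(n = -2, family = "binary"),
               class = "truncsim_invalid_parameter")
  expect_error(scenario_params(n = 100, family = "continuous", sigma = 0),
               class = "truncsim_invalid_parameter")
  expect_error(scenario_params(n = 100, family = "continuous",
                               n_iterations = 0),
               class = "truncsim_invalid_parameter")
  expect_error(scenario_params(n = 100, family = "continuous",
                               alpha_R = NA_real_),
               class = "truncsim_invalid_parameter")
})

test_that("defaults follow the outcome family", {
  pc <- scenario_params(n = 100, family = "continuous")
  expect_equal(pc$beta_0, 3300)
  expect_equal(pc$beta_U, -116)
  expect_equal(pc$sigma, 580)
  pb <- scenario_params(n = 100, family = "binary")
  expect_equal(pb$beta_0, log(0.1))
  expect_equal(pb$beta_U, log(1.2))
})

test_that("treatment allocation is exactly equal and deterministic", {
  for (n in c(4L, 100L, 1000L)) {
    R <- assign_treatment(n)
    expect_length(R, n)
    expect_equal(sum(R == 1), n / 2)
    expect_equal(sum(R == 0), n / 2)
  }
  expect_identical(assign_treatment(10), assign_treatment(10))
  expect_error(assign_treatment(3), class = "truncsim_invalid_parameter")
  expect_error(assign_treatment(0), class = "truncsim_invalid_parameter")
})

test_that("intermediate event rate matches the inverse-logit of the linear predictor", {
  # with no treatment or confounder effect the rate is plogis(log 0.2) = 1/6
  p <- scenario_params(n = 2e5, family = "continuous", alpha_R = 0,
                       alpha_U = 0)
  set.seed(101)
  S <- simulate_intermediate(p, rep(0L, p$n), rnorm(p$n))
  expect_equal(mean(S), 1 / 6, tolerance = 0.02)

  # core control-arm marginal rate (alpha_U = log 0.8, u ~ N(0,1)) is ~17%
  p2 <- scenario_params(n = 4e5, family = "continuous")
  set.seed(102)
  S2 <- simulate_intermediate(p2, rep(0L, p2$n), rnorm(p2$n))
  expect_equal(mean(S2), 0.17, tolerance = 0.015)

  # saturating intercept forces the event for everyone
  p3 <- scenario_params(n = 1000, family = "continuous", alpha_0 = 20)
  set.seed(103)
  expect_true(all(simulate_intermediate(p3, rep(0L, 1000), rnorm(1000)) == 1))

  expect_error(simulate_intermediate(p3, rep(0L, 10), rnorm(9)),
               class = "truncsim_invalid_parameter")
})

test_that("continuous outcomes have the specified mean structure", {
  p <- scenario_params(n = 2e5, family = "continuous", beta_R = 0)
  set.seed(104)
  u <- rnorm(p$n)
  R <- rep(0L, p$n)
  Y <- simulate_continuous_outcome(p, R, u, rep(1L, p$n))
  # marginal control mean 3300, SD sqrt(580^2 + 116^2)
  expect_equal(mean(Y), 3300, tolerance = 5)
  expect_equal(sd(Y), sqrt(580^2 + 116^2), tolerance = 5)
  # sigma -> 0 limit: Y equals its mean; at u = 1 in control that is 3300 - 116
  p_small <- scenario_params(n = 2, family = "continuous", sigma = 1e-9)
  expect_equal(simulate_continuous_outcome(p_small, c(1L, 0L), c(0, 1), c(1L, 1L)),
               c(3300, 3300 - 116), tolerance = 1e-5)
  expect_error(simulate_continuous_outcome(
    scenario_params(n = 10, family = "binary"), rep(0L, 10), rnorm(10), rep(1L, 10)),
    class = "truncsim_invalid_state")
})

test_that("binary outcome rates match the logistic submodel", {
  # intercept-only: plogis(log 0.1) = 1/11
  p <- scenario_params(n = 2e5, family = "binary", beta_U = 0)
  set.seed(105)
  Y <- simulate_binary_outcome(p, rep(0L, p$n), rnorm(p$n), rep(1L, p$n))
  expect_equal(mean(Y), 1 / 11, tolerance = 0.01)

  # symmetric intercept 0 with symmetric confounder: marginal rate 50%
  p2 <- scenario_params(n = 2e5, family = "binary", beta_0 = 0)
  set.seed(106)
  Y2 <- simulate_binary_outcome(p2, rep(0L, p2$n), rnorm(p2$n), rep(1L, p2$n))
  expect_equal(mean(Y2), 0.5, tolerance = 0.01)

  # saturating negative intercept: essentially no events
  p3 <- scenario_params(n = 1e4, family = "binary", beta_0 = -20)
  set.seed(107)
  expect_equal(sum(simulate_binary_outcome(p3, rep(0L, 1e4), rnorm(1e4),
                                           rep(1L, 1e4))), 0)
  expect_error(simulate_binary_outcome(
    scenario_params(n = 10, family = "continuous"), rep(0L, 10), rnorm(10), rep(1L, 10)),
    class = "truncsim_invalid_state")
})

test_that("simulate_trial is deterministic given a seed and has the right shape", {
  p <- scenario_params(n = 100, family = "binary", alpha_R = log(1.5),
                       beta_R = log(1.2))
  t1 <- simulate_trial(p, seed = 7)
  t2 <- simulate_trial(p, seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100)
  expect_named(t1, c("R", "u", "S", "Y"))
  expect_equal(sum(t1$R), 50)
  expect_false(identical(t1, simulate_trial(p, seed = 8)))
})

test_that("truncation selects on the confounder in the expected direction", {
  # alpha_U < 0: survivors have below-average u; and with alpha_R > 0 the
  # selection is weaker (u higher) in the treated arm than the control arm
  p <- scenario_params(n = 2e5, family = "continuous", alpha_R = log(2))
  trial <- simulate_trial(p, seed = 9)
  surv <- truncate_trial(trial)
  expect_lt(mean(surv$u), 0)
  expect_lt(mean(surv$u[surv$R == 0]), mean(surv$u[surv$R == 1]))
  # sign of the u-S association is negative when alpha_U < 0
  expect_lt(cor(trial$u, trial$S), 0)
})

test_that("survivor count in the treated arm increases with alpha_R", {
  rates <- sapply(c(1, 1.5, 2, 5), function(or) {
    p <- scenario_params(n = 2e4, family = "continuous", alpha_R = log(or))
    trial <- simulate_trial(p, seed = 11)
    mean(trial$S[trial$R == 1])
  })
  expect_true(all(diff(rates) > 0))
})
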
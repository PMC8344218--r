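test_that("truncation returns exactly the survivor subgroup", {
  trial <- tibble::tibble(R = c(1, 1, 0, 0), u = 0, S = c(1, 0, 1, 1),
                          Y = 1:4)
  surv <- truncate_trial(trial)
  expect_equal(nrow(surv), 3)
  expect_equal(surv$Y, c(1, 3, 4))

  all_in <- tibble::tibble(R = c(1, 0), u = 0, S = 1, Y = c(1, 2))
  expect_equal(nrow(truncate_trial(all_in)), 2)

  one_arm_empty <- tibble::tibble(R = c(1, 1, 0), u = 0, S = c(0, 0, 1), Y = 1:3)
  surv2 <- truncate_trial(one_arm_empty)
  expect_equal(sum(surv2$R == 1), 0)
  expect_equal(sum(surv2$R == 0), 1)
})

test_that("difference in means matches the pooled-t closed form", {
  # identical samples: estimate 0, p = 1
  r0 <- difference_in_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$estimate, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$computable)

  # frozen closed-form case: pooled SD 1, SE sqrt(2/3), t = sqrt(3/2), df 4
  r <- difference_in_means(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r$estimate, 1)
  expect_equal(r$model_se, sqrt(2 / 3))
  expect_equal(r$p_value, 2 * pt(-1 / sqrt(2 / 3), 4))
  tc <- qt(0.975, 4)
  expect_equal(r$ci_low, 1 - tc * sqrt(2 / 3))
  expect_equal(r$ci_high, 1 + tc * sqrt(2 / 3))

  # agreement with the standard equal-variance t-test on random samples
  set.seed(21)
  for (i in 1:20) {
    y1 <- rnorm(sample(2:30, 1), sd = 2)
    y0 <- rnorm(sample(2:30, 1))
    mine <- difference_in_means(y1, y0)
    ref <- t.test(y1, y0, var.equal = TRUE)
    expect_equal(mine$p_value, unname(ref$p.value))
    expect_equal(c(mine$ci_low, mine$ci_high), unname(ref$conf.int),
                 ignore_attr = TRUE)
  }
})

test_that("difference in means flags arms with fewer than two survivors", {
  r <- difference_in_means(c(1, 2, 3), c(5))
  expect_false(r$computable)
  expect_true(is.na(r$estimate) && is.na(r$p_value))
  expect_equal(r$n_control, 1)
  r2 <- difference_in_means(numeric(0), c(1, 2))
  expect_false(r2$computable)
  expect_error(difference_in_means("a", 1:3), class = "truncsim_invalid_input")
})

test_that("sample log OR equals the logistic-regression MLE with Woolf SE", {
  r <- fit_logistic_or(c(10, 40, 5, 45))
  expect_equal(r$log_or, log(2.25))
  expect_equal(r$wald_se, sqrt(1 / 10 + 1 / 40 + 1 / 5 + 1 / 45))

  # symmetry: equal arms give log OR 0
  expect_equal(fit_logistic_or(c(7, 13, 7, 13))$log_or, 0)

  # fuzz: cross-product formula == iterative logistic fit
  set.seed(22)
  for (i in 1:25) {
    tab <- random_table()
    mine <- fit_logistic_or(tab)
    ref <- glm_logor_oracle(tab[1], tab[2], tab[3], tab[4])
    expect_equal(mine$log_or, unname(ref["log_or"]), tolerance = 1e-6)
    # glm's vcov carries its iterative convergence tolerance
    expect_equal(mine$wald_se, unname(ref["se"]), tolerance = 1e-4)
  }

  expect_error(fit_logistic_or(c(0, 50, 10, 40)), class = "truncsim_separation")
})

test_that("separation is any zero cell: none or all events in an arm", {
  expect_true(detect_separation(c(0, 50, 10, 40)))
  expect_true(detect_separation(c(50, 0, 10, 40)))
  expect_true(detect_separation(c(10, 40, 0, 50)))
  expect_true(detect_separation(c(10, 40, 50, 0)))
  expect_true(detect_separation(c(0, 0, 10, 40)))  # empty treated arm
  expect_false(detect_separation(c(10, 40, 20, 30)))
  expect_error(detect_separation(c(-1, 2, 3, 4)), class = "truncsim_invalid_input")
})

test_that("analyse_trial dispatches by family and never raises on degeneracy", {
  pb <- scenario_params(n = 60, family = "binary", beta_0 = -20)
  trial <- simulate_trial(pb, seed = 31)  # essentially no outcome events
  res <- analyse_trial(trial, "binary")
  expect_false(res$or_estimable)
  expect_true(is.na(res$log_or))
  expect_false(is.na(res$p_fisher))  # Fisher always computable

  pc <- scenario_params(n = 2000, family = "continuous", alpha_0 = 20,
                        beta_R = 0)
  trialc <- simulate_trial(pc, seed = 32)  # everyone survives
  resc <- analyse_trial(trialc, "continuous")
  expect_true(resc$computable)
  expect_equal(resc$n_treated + resc$n_control, 2000)
  expect_lt(abs(resc$estimate), 4 * resc$model_se)

  # determinism of the full pipeline on a fixed trial
  expect_identical(analyse_trial(trial, "binary"), analyse_trial(trial, "binary"))

  expect_error(analyse_trial(trialc, "binary"), class = "truncsim_invalid_state")
})
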
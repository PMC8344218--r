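test_that("scalar performance measures match their definitions", {
  expect_equal(bias(c(4, 5, 6), 5), 0)
  expect_equal(bias(c(5, 5, 5), 3), 2)
  expect_equal(empirical_se(c(1, 2, 3)), 1)
  expect_equal(empirical_se(rep(2, 10)), 0)
  expect_equal(model_se(c(3, 4)), sqrt(12.5))
  expect_equal(model_se(c(3, 4), method = "mean"), 3.5)
  expect_equal(model_se(rep(2.5, 5)), 2.5)
  expect_equal(coverage(c(0, 1, 5), c(2, 3, 6), 1.5), 2 / 3)
  expect_equal(coverage(c(0, 0), c(2, 2), 1), 1)
  expect_equal(ror(c(0.1, 0.1), 0.1), 1)
  expect_equal(ror(c(0.2, 0.2), 0.1, method = "geometric"), exp(0.1))
  expect_equal(ror(log(c(2, 4)), log(2)), 3 / 2)  # mean OR 3 over true OR 2
  expect_error(bias(numeric(0), 1), class = "truncsim_invalid_input")
})

test_that("rejection rate honours both denominator conventions", {
  p <- c(0.01, 0.2, NA, 0.03)
  expect_equal(rejection_rate(p), 2 / 3)
  expect_equal(rejection_rate(p, denominator = "all"), 2 / 4)
  expect_equal(rejection_rate(rep(0.001, 5)), 1)
  expect_equal(rejection_rate(rep(0.5, 5)), 0)
  expect_true(is.na(rejection_rate(c(NA_real_, NA_real_))))
  expect_equal(rejection_rate(c(NA_real_, NA_real_), denominator = "all"), 0)
  # uniform-null calibration
  set.seed(61)
  expect_lt(abs(rejection_rate(runif(1e5)) - 0.05), 0.005)
})

test_that("empirical SE is calibrated on known normal draws", {
  set.seed(62)
  expect_equal(empirical_se(rnorm(1e5, sd = 2)), 2, tolerance = 0.02)
})

test_that("summarise_scenario matches a hand-computed fixture", {
  params <- scenario_params(n = 100, family = "continuous", beta_R = 50)
  rec <- tibble::tibble(
    estimate = c(40, 60, 55, NA),
    model_se = c(10, 12, 11, NA),
    ci_low = c(20, 40, 35, NA),
    ci_high = c(60, 80, 75, NA),
    p_value = c(0.04, 0.20, 0.30, NA),
    n_treated = c(10, 12, 11, 1), n_control = c(9, 11, 10, 5),
    computable = c(TRUE, TRUE, TRUE, FALSE)
  )
  s <- summarise_scenario(rec, params)
  expect_equal(s$n_iterations, 4)
  expect_equal(s$n_estimable, 3)
  expect_equal(s$n_separated, 1)
  expect_equal(s$n_estimable + s$n_separated, s$n_iterations)
  expect_equal(s$bias, mean(c(40, 60, 55)) - 50)
  expect_equal(s$bias_sd_units, s$bias / 580)
  expect_equal(s$empirical_se, sd(c(40, 60, 55)))
  expect_equal(s$model_se, sqrt(mean(c(10, 12, 11)^2)))
  expect_equal(s$coverage, 1)  # all three computable intervals contain 50
  expect_equal(s$rej_t, 1 / 3)
  expect_equal(s$n_incomputable_t, 1)
  expect_equal(s$bias_mc_se, s$empirical_se / sqrt(3))

  # all-iterations denominator counts the missing p as a non-rejection
  s_all <- summarise_scenario(rec, params, denominator = "all")
  expect_equal(s_all$rej_t, 1 / 4)
})

test_that("binary summaries keep the separation accounting conserved", {
  params <- scenario_params(n = 100, family = "binary", beta_R = log(1.2))
  rec <- tibble::tibble(
    log_or = c(0.5, NA, 0.1), model_se = c(0.4, NA, 0.3),
    ci_low = c(-0.3, NA, -0.5), ci_high = c(1.3, NA, 0.7),
    p_chi2 = c(0.03, NA, 0.6), p_chi2_adj = c(0.04, NA, 0.61),
    p_fisher = c(0.04, 0.9, 0.7),
    a = c(5, 0, 3), b = c(20, 25, 22), c = c(4, 2, 3), d = c(21, 23, 22),
    n_treated = 25, n_control = 25,
    or_estimable = c(TRUE, FALSE, TRUE), chi2_computable = c(TRUE, FALSE, TRUE)
  )
  s <- summarise_scenario(rec, params)
  expect_equal(s$n_estimable + s$n_separated, s$n_iterations)
  expect_equal(s$n_separated, 1)
  expect_equal(s$ror, mean(exp(c(0.5, 0.1))) / 1.2)
  expect_equal(s$coverage, 1)  # both computable intervals contain log 1.2
  expect_equal(s$rej_chi2, 1 / 2)
  expect_equal(s$rej_fisher, 1 / 3)
  expect_equal(s$n_incomputable_chi2, 1)

  # degenerate: every iteration separated -- summary flags, no crash
  rec_all_sep <- rec[2, ]
  s2 <- summarise_scenario(rec_all_sep, params)
  expect_equal(s2$n_estimable, 0)
  expect_true(is.na(s2$bias) && is.na(s2$ror))
})
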
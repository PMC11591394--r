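test_that("the Hajek estimator reduces to arm means on complete data", {
  cfg <- synthetic_config(n = 80, missingness = no_missingness())
  p <- prepare_analysis(cfg, seed = 41)
  v_tel <- estimate_value(fixed_rule("telehealth"), p$ds, p$r)
  v_inp <- estimate_value(fixed_rule("in_person"), p$ds, p$r)
  expect_equal(as.numeric(v_tel), mean(p$ds$Y[p$ds$A == 1]),
               tolerance = 1e-12)
  expect_equal(as.numeric(v_inp), mean(p$ds$Y[p$ds$A == 0]),
               tolerance = 1e-12)
  expect_identical(attr(v_tel, "n_matched"), sum(p$ds$A == 1))

  # three-subject worked example (covariates varied so standardization
  # is well defined)
  toy <- data.frame(age = c(30, 40, 50), white = c(0, 1, 0),
                    disability = c(1, 0, 0), rural = c(0, 1, 1),
                    low_income = c(1, 0, 1), pcl_baseline = c(40, 50, 60),
                    arm = c(1, 1, 0), pcl_6month = c(10, 20, 30))
  ds3 <- assemble_analysis_dataset(toy)
  expect_equal(as.numeric(estimate_value(fixed_rule("telehealth"), ds3)),
               15)
})

test_that("value estimation fails cleanly with no matched subject", {
  cfg <- synthetic_config(n = 30, missingness = no_missingness())
  p <- prepare_analysis(cfg, seed = 42)
  trial <- p$trial
  trial$arm <- 0  # nobody received telehealth
  trial$pcl_6month <- abs(trial$pcl_6month) %% 80
  ds <- assemble_analysis_dataset(trial)
  expect_error(estimate_value(fixed_rule("telehealth"), ds,
                              propensities = 0.5), "undefined|no observed")
})

test_that("contrasts difference the shared-data values", {
  cfg <- synthetic_config(n = 100, missingness = no_missingness())
  p <- prepare_analysis(cfg, seed = 43)
  expect_identical(contrast_values(fixed_rule("telehealth"),
                                   fixed_rule("telehealth"), p$ds, p$r), 0)
  expect_equal(contrast_values(fixed_rule("telehealth"),
                               fixed_rule("in_person"), p$ds, p$r),
               mean(p$ds$Y[p$ds$A == 1]) - mean(p$ds$Y[p$ds$A == 0]),
               tolerance = 1e-12)
})

test_that("values are affine-equivariant in the outcome", {
  cfg <- scenario_default(n = 200)
  p <- prepare_analysis(cfg, seed = 44)
  rule <- decision_rule(0.2, rnorm(6))
  v <- as.numeric(estimate_value(rule, p$ds, p$r))

  ds2 <- p$ds
  ds2$Y <- 0.5 * p$ds$Y + 7
  v2 <- as.numeric(estimate_value(rule, ds2, p$r))
  expect_equal(v2, 0.5 * v + 7, tolerance = 1e-10)
  c1 <- contrast_values(rule, fixed_rule("in_person"), p$ds, p$r)
  c2 <- contrast_values(rule, fixed_rule("in_person"), ds2, p$r)
  expect_equal(c2, 0.5 * c1, tolerance = 1e-10)
})

test_that("bootstrap inference is deterministic, Wald and robust", {
  cfg <- scenario_default(n = 150)
  p <- prepare_analysis(cfg, seed = 45)
  stat <- function(ds) {
    r <- suppressMessages(
      observation_weights(fit_observation_model(ds), ds))
    as.numeric(estimate_value(fixed_rule("telehealth"), ds, r))
  }
  b1 <- bootstrap_inference(stat, p$ds, B = 80, seed = 9)
  b2 <- bootstrap_inference(stat, p$ds, B = 80, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_equal(unname(b1$ci_upper - b1$estimate), 1.96 * unname(b1$se),
               tolerance = 1e-12)
  expect_true(b1$ci_lower <= b1$estimate && b1$estimate <= b1$ci_upper)

  const <- bootstrap_inference(function(ds) 3.5, p$ds, B = 50, seed = 1)
  expect_identical(unname(const$se), 0)
  expect_equal(unname(const$ci_lower), 3.5)

  # > 10% failures is an inference error; occasional failures are dropped
  flaky <- local({
    k <- 0
    function(ds) { k <<- k + 1; if (k %% 2 == 0) stop("boom"); 1 }
  })
  expect_error(bootstrap_inference(flaky, p$ds, B = 50, seed = 2),
               "10%")
})

test_that("the performance table has the documented shape", {
  cfg <- scenario_default(n = 122)
  p <- prepare_analysis(cfg, seed = 46)
  rule <- fit_owl(p$ds$Z, p$ds$A, p$w, mean(p$w$w[p$w$w > 0]) * 0.1,
                  standardization = p$ds$std_params)
  perf <- suppressMessages(
    performance_table(p$ds, rule, B = 60, seed = 3))
  expect_identical(nrow(perf), 5L)
  expect_identical(perf$parameter[1:3],
                   c("V_dopt", "V_dopt - V_telehealth",
                     "V_dopt - V_inperson"))
  vals <- perf[1:3, ]
  expect_true(all(vals$ci_lower <= vals$estimate + 1e-12 &
                    vals$estimate <= vals$ci_upper + 1e-12))
  counts <- perf[4:5, ]
  expect_identical(sum(counts$estimate), 122)
  expect_match(vals$formatted[1],
               "^-?\\d+\\.\\d\\d \\(-?\\d+\\.\\d\\d, -?\\d+\\.\\d\\d\\)$")

  # contrasts of the rule against itself vanish when the "rule" is fixed
  perf_tel <- suppressMessages(
    performance_table(p$ds, fixed_rule("telehealth"), B = 40, seed = 4))
  expect_equal(perf_tel$estimate[2], 0, tolerance = 1e-12)
})

test_that("value estimates are unbiased for the generator truth", {
  cfg <- synthetic_config(n = 200, missingness = no_missingness())
  rule <- fixed_rule("in_person")
  truth <- true_policy_value(rule, cfg, n_mc = 2e5, seed = 2)
  vs <- vapply(1:200, function(b) {
    ds <- assemble_analysis_dataset(simulate_trial(cfg, seed = 3000 + b))
    as.numeric(estimate_value(rule, ds))
  }, 0.0)
  expect_lt(abs(mean(vs) - truth), 3 * sd(vs) / sqrt(length(vs)))
})
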
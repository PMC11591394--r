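test_that("generated covariate marginals match their configured targets", {
  cfg <- synthetic_config(n = 10000)
  covs <- generate_covariates(cfg, seed = 42)

  expect_lt(abs(mean(covs$age) - 42.80), 3 * 11.61 / sqrt(10000))
  expect_lt(abs(sd(covs$age) - 11.61), 3 * 11.61 / sqrt(2 * 10000))
  expect_true(all(covs$age >= 18 & covs$age <= 90))

  for (spec in list(c("white", 0.279), c("disability", 0.639),
                    c("rural", 0.344), c("low_income", 0.492))) {
    p <- as.numeric(spec[2])
    expect_lt(abs(mean(covs[[spec[1]]]) - p),
              3 * sqrt(p * (1 - p) / 10000))
  }
  expect_lt(abs(mean(covs$pcl_baseline) - 52.74), 3 * 12.81 / sqrt(10000))
  expect_true(all(covs$pcl_baseline >= 0 & covs$pcl_baseline <= 80))
})

test_that("degenerate generator inputs are handled or rejected", {
  cfg <- synthetic_config()
  empty <- generate_covariates(cfg, n = 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), c("age", "white", "disability", "rural",
                                   "low_income", "pcl_baseline"))
  expect_error(synthetic_config(arm_ratio = 1), "arm_ratio")
  expect_error(synthetic_config(covariates = list(p_white = 1.2)),
               "probability")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(control_surface = c(1, 2)), "entries")
  expect_length(randomize_arms(1, 0.5, seed = 1), 1)
  expect_error(randomize_arms(10, 1.5), "arm_ratio")
})

test_that("randomization is reproducible and has the right rate", {
  a1 <- randomize_arms(122, 0.5, seed = 7)
  a2 <- randomize_arms(122, 0.5, seed = 7)
  expect_identical(a1, a2)
  big <- randomize_arms(100000, 0.5, seed = 8)
  expect_lt(abs(mean(big) - 0.5), 3 * 0.5 / sqrt(100000))
})

test_that("outcome generation follows the configured surfaces", {
  cfg0 <- synthetic_config(
    n = 50, noise_sd = 0,
    interaction_surface = c(intercept = 0, age = 0, white = 0,
                            disability = 0, rural = 0, low_income = 0,
                            pcl_baseline = 0))
  covs <- generate_covariates(cfg0, n = 50, seed = 1)
  y_tel <- generate_outcomes(covs, rep(1, 50), cfg0, seed = 2)
  y_inp <- generate_outcomes(covs, rep(0, 50), cfg0, seed = 3)
  expect_equal(y_tel, y_inp)  # null effect, no noise

  cfg_hi <- synthetic_config(
    n = 20, noise_sd = 0,
    control_surface = c(intercept = 90, age = 0, white = 0,
                        disability = 0, rural = 0, low_income = 0,
                        pcl_baseline = 0),
    interaction_surface = c(intercept = 0, age = 0, white = 0,
                            disability = 0, rural = 0, low_income = 0,
                            pcl_baseline = 0))
  covs2 <- generate_covariates(cfg_hi, n = 20, seed = 1)
  expect_true(all(generate_outcomes(covs2, rep(0, 20), cfg_hi,
                                    seed = 2) == 80))
  expect_error(generate_outcomes(covs2, rep(0, 3), cfg_hi), "equal length")
})

test_that("default marginal outcome SD is close to the emulated 21.84", {
  cfg <- synthetic_config(n = 10000)
  trial <- simulate_trial(cfg, seed = 11)
  s <- sd(trial$pcl_6month, na.rm = TRUE)
  expect_lt(abs(s - 21.84) / 21.84, 0.20)
  expect_true(all(trial$pcl_6month >= 0 & trial$pcl_6month <= 80,
                  na.rm = TRUE))
})

test_that("missingness model hits its rate and is covariate-driven", {
  # MCAR: intercept-only at logit of the observation rate
  cfg_mcar <- synthetic_config(
    n = 10000,
    missingness = c(intercept = qlogis(0.6475), age = 0, white = 0,
                    disability = 0, rural = 0, low_income = 0,
                    pcl_baseline = 0, arm = 0))
  covs <- generate_covariates(cfg_mcar, seed = 3)
  arms <- randomize_arms(10000, 0.5, seed = 4)
  y <- generate_outcomes(covs, arms, cfg_mcar, seed = 5)
  miss <- impose_missingness(y, covs, arms, cfg_mcar, seed = 6)
  expect_lt(abs(mean(miss$observed) - 0.6475),
            3 * sqrt(0.6475 * 0.3525 / 10000))
  expect_true(all(miss$prob > 0 & miss$prob < 1))
  expect_true(all(is.na(miss$outcome[!miss$observed])))

  # effectively no missingness at a huge intercept
  cfg_none <- synthetic_config(n = 1000, missingness = no_missingness())
  m2 <- impose_missingness(y[1:1000], covs[1:1000, ], arms[1:1000],
                           cfg_none, seed = 6)
  expect_true(all(m2$observed))

  # MAR via age: observed and missing groups differ in mean age
  cfg_mar <- synthetic_config(
    n = 5000,
    missingness = c(intercept = 0.7, age = -0.8, white = 0,
                    disability = 0, rural = 0, low_income = 0,
                    pcl_baseline = 0, arm = 0))
  covs3 <- generate_covariates(cfg_mar, seed = 7)
  arms3 <- randomize_arms(5000, 0.5, seed = 8)
  y3 <- generate_outcomes(covs3, arms3, cfg_mar, seed = 9)
  m3 <- impose_missingness(y3, covs3, arms3, cfg_mar, seed = 10)
  tt <- t.test(covs3$age[m3$observed], covs3$age[!m3$observed])
  expect_lt(tt$p.value, 1e-6)
  expect_lt(mean(covs3$age[m3$observed]), mean(covs3$age[!m3$observed]))
})

test_that("a fixed seed reproduces the full trial bit-identically", {
  cfg <- synthetic_config(n = 500)
  t1 <- simulate_trial(cfg, seed = 99)
  t2 <- simulate_trial(cfg, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_trial(cfg, seed = 100)
  expect_false(identical(t1$pcl_6month, t3$pcl_6month))
})

test_that("ground truth orders policies correctly and regret is coherent", {
  cfg <- scenario_default(n = 122)
  gt <- ground_truth(cfg, n_mc = 20000, seed = 5)
  expect_lte(gt$optimal_value, min(gt$arm_values) + 1e-10)
  expect_equal(gt$regret_of(gt$true_rule), 0, tolerance = 1e-12)

  # any rule has nonnegative regret (up to MC error, here exact given
  # the shared covariate draw)
  set.seed(21)
  for (i in 1:5) {
    rnd <- decision_rule(rnorm(1), rnorm(6),
                         standardization = gt$true_rule$standardization)
    expect_gte(gt$regret_of(rnd), 0)
  }

  # a fixed-arm rule is optimal when the effect is uniform in its favor
  cfg_tel <- scenario_null(n = 100, better = "telehealth")
  expect_lt(regret(fixed_rule("telehealth"), cfg_tel, n_mc = 20000,
                   seed = 2), 1e-10)
  expect_warning(regret(fixed_rule("telehealth"), cfg_tel, n_mc = 500),
                 "unstable")
})

test_that("anti-optimal regret matches the closed form c * sqrt(2/pi)", {
  eff <- 5
  cfg <- scenario_single_covariate(effect = eff)
  gt <- ground_truth(cfg, n_mc = 1e5, seed = 31)
  anti <- decision_rule(-gt$true_rule$intercept, -gt$true_rule$slopes,
                        standardization = gt$true_rule$standardization)
  closed <- eff * sqrt(2 / pi)
  mc_se <- eff * sd(abs(rnorm(1e5))) / sqrt(1e5)
  expect_lt(abs(gt$regret_of(anti) - closed), 3 * mc_se)
})

test_that("trial CSV round-trips with empty fields for missing outcomes", {
  cfg <- synthetic_config(n = 60)
  trial <- simulate_trial(cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trial, path)
  header <- readLines(path, n = 1)
  expect_identical(header, paste(trial_csv_columns(), collapse = ","))
  back <- read_trial_csv(path)
  expect_equal(back$pcl_6month, trial$pcl_6month)
  expect_equal(back$age, trial$age, tolerance = 1e-12)
  expect_identical(is.na(back$pcl_6month), is.na(trial$pcl_6month))
})
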
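test_that("the reward transform anchors at the instrument maximum", {
  expect_equal(compute_rewards(80), 0)
  expect_equal(compute_rewards(0), 80)
  expect_equal(compute_rewards(52.74), 27.26)
  expect_identical(compute_rewards(c(10, NA)), c(70, NA))
  expect_error(compute_rewards(81), "\\[0, 80\\]")
  expect_error(compute_rewards(-0.5), "\\[0, 80\\]")
})

test_that("OWL subject weights combine reward, IPW and propensity", {
  w <- owl_weights(B = 40, r = 1, A = 1, propensities = 0.5)
  expect_equal(w$w, 80)

  # missing outcome: zero weight regardless of (NA) reward
  w2 <- owl_weights(B = c(40, NA), r = c(1, 0), A = c(1, 0),
                    propensities = 0.5)
  expect_equal(w2$w[2], 0)

  # empirical propensities from the realized 62/60 split
  A <- rep(c(1, 0), c(62, 60))
  w3 <- owl_weights(B = rep(1, 122), r = rep(1, 122), A = A)
  expect_equal(unique(w3$propensity[A == 1]), 62 / 122)
  expect_equal(w3$w[1], 1 / (62 / 122), tolerance = 1e-12)

  expect_error(owl_weights(B = 1, r = 1, A = 1, propensities = 1),
               "positivity|propensities")
  expect_error(owl_weights(B = rep(1, 3), r = rep(1, 3), A = c(1, 1, 1)),
               "both arms")
})

test_that("degenerate OWL fits behave as documented", {
  Z <- matrix(rnorm(12 * 6), 12)
  A <- rep(c(0, 1), 6)
  expect_warning(rule <- fit_owl(Z, A, rep(0, 12), 0.5), "zero")
  expect_equal(rule$intercept, 0)
  expect_true(all(rule$slopes == 0))
  expect_true(all(apply_rule(rule, Z)$assignment == 1))  # tie -> telehealth

  # two subjects, heavy penalty forcing beta = 0: the weighted-majority
  # arm wins via the intercept; cross-checked against a 1-D grid search
  # over b0 alone
  Z2 <- matrix(0, 2, 6)
  rule2 <- fit_owl(Z2, c(1, 0), w = c(10, 1), lambda = 10)
  expect_true(all(apply_rule(rule2, Z2)$assignment == 1))
  b0s <- seq(-3, 3, by = 0.001)
  h <- vapply(b0s, function(b)
    mean(c(10, 1) * pmax(0, 1 - c(1, -1) * b)), 0.0)
  expect_equal(rule2$intercept, b0s[which.min(h)], tolerance = 1e-2)

  expect_error(fit_owl(Z, A, rep(1, 12), -1), "lambda")
})

test_that("the OWL fit is a certified, deterministic convex minimizer", {
  set.seed(99)
  inst <- random_owl_instance(40)
  A <- as.integer(inst$a == 1)
  f1 <- fit_owl(inst$Z, A, inst$w, 0.3)
  f2 <- fit_owl(inst$Z, A, inst$w, 0.3)
  expect_equal(f1$slopes, f2$slopes, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)

  # certified near-optimality and convexity sanity
  expect_lt(attr(f1, "duality_gap") /
              max(1, attr(f1, "objective")), 1e-6)
  obj_zero <- owl_objective(rep(0, 7), inst$Z, inst$a, inst$w, 0.3)
  expect_lte(attr(f1, "objective"), obj_zero)

  # scaling weights and penalty together leaves assignments unchanged
  f3 <- fit_owl(inst$Z, A, 7.3 * inst$w, 7.3 * 0.3)
  expect_identical(apply_rule(f3, inst$Z)$assignment,
                   apply_rule(f1, inst$Z)$assignment)
})

test_that("the fit matches an independent subgradient minimizer", {
  set.seed(123)
  for (i in 1:8) {
    inst <- random_owl_instance(sample(10:30, 1))
    if (all(inst$w == 0) || length(unique(inst$a[inst$w > 0])) < 2) next
    lambda <- 2^runif(1, -8, 4)
    fit <- suppressWarnings(
      fit_owl(inst$Z, as.integer(inst$a == 1), inst$w, lambda))
    ref <- subgradient_owl(inst$Z, inst$a, inst$w, lambda)
    expect_lt(abs(attr(fit, "objective") - ref$value) /
                max(1, abs(ref$value)), 1e-4)
  }
})

test_that("large penalties collapse the rule to the weighted-majority arm", {
  p <- prepare_analysis(synthetic_config(n = 150), seed = 71)
  w <- p$w$w
  big <- fit_owl(p$ds$Z, p$ds$A, w, 50 * mean(w[w > 0]))
  expect_lt(max(abs(big$slopes)), 0.05)
  a <- ifelse(p$ds$A == 1, 1, -1)
  majority <- as.integer(sum(w[a == 1]) >= sum(w[a == -1]))
  expect_true(all(apply_rule(big, p$ds$Z)$assignment == majority))
})

test_that("rules score and assign by the printed indicator convention", {
  printed <- decision_rule(-0.23, c(-0.84, -0.96, 0.02, 0.08, 0.63, -0.02))
  at0 <- apply_rule(printed, rep(0, 6))
  expect_equal(at0$score, -0.23)
  expect_identical(at0$assignment, 0L)
  at1 <- apply_rule(printed, rep(1, 6))
  expect_equal(at1$score, -1.32)
  expect_identical(at1$assignment, 0L)

  zero <- decision_rule(0, rep(0, 6))
  expect_identical(apply_rule(zero, rnorm(6))$assignment, 1L)

  expect_error(apply_rule(printed, rep(0, 5)), "entries")
  expect_error(decision_rule(0, rep(0, 4)), "slopes")
  expect_error(decision_rule(0, rep(0, 6), tie = "in_person"), "tie")

  expect_match(format_rule(printed), "I\\(-0.23")
  expect_match(format_rule(printed), "0.84 x Age")
})

test_that("fixed rules assign everyone to their arm", {
  Z <- matrix(rnorm(30), 5)
  expect_true(all(apply_rule(fixed_rule("telehealth"),
                             cbind(Z, Z)[, 1:6])$assignment == 1))
  expect_true(all(apply_rule(fixed_rule("in_person"),
                             cbind(Z, Z)[, 1:6])$assignment == 0))
})

test_that("jackknife lambda selection matches a hand-rolled loop", {
  cfg <- synthetic_config(n = 6, missingness = no_missingness())
  p <- prepare_analysis(cfg, seed = 81)
  if (length(unique(p$ds$A)) < 2) skip("degenerate tiny draw")
  tun <- select_lambda(p$ds, p$r, grid = 0.5,
                       scale_by_mean_weight = FALSE)
  expect_identical(tun$selected, 0.5)  # single candidate always selected

  # manual leave-one-out loop
  w <- p$w$w
  d_manual <- rep(NA_integer_, 6)
  for (i in 1:6) {
    rule_i <- suppressWarnings(
      fit_owl(p$ds$Z[-i, ], p$ds$A[-i], w[-i], 0.5))
    d_manual[i] <- apply_rule(rule_i, p$ds$Z[i, ])$assignment
  }
  expect_identical(tun$assignments[, 1], d_manual)
  expect_equal(tun$cv_value[1], hajek_value(p$ds, d_manual, p$r),
               tolerance = 1e-12)
})

test_that("lambda ties break toward the larger candidate", {
  # a uniformly better arm keeps the weighted majority stable under
  # leave-one-out, so collapsed candidates remain scorable
  p <- prepare_analysis(scenario_null(n = 60, better = "in_person"),
                        seed = 82)
  # two enormous penalties give identical collapsed assignments
  tun <- select_lambda(p$ds, p$r, grid = c(5e4, 1e5),
                       scale_by_mean_weight = FALSE)
  expect_identical(tun$cv_value[1], tun$cv_value[2])
  expect_identical(tun$selected, 1e5)
  expect_error(select_lambda(p$ds, p$r, grid = numeric(0)), "nonempty")
})

test_that("selected penalty beats the collapsing penalty on regret", {
  wins <- vapply(1:15, function(b) {
    cfg <- scenario_strong_interaction(n = 150, seed = b)
    p <- prepare_analysis(cfg)
    tun <- select_lambda(p$ds, p$r)
    sel <- fit_owl(p$ds$Z, p$ds$A, p$w, tun$selected,
                   standardization = p$ds$std_params)
    big <- fit_owl(p$ds$Z, p$ds$A, p$w, max(tun$grid),
                   standardization = p$ds$std_params)
    gt <- ground_truth(cfg, n_mc = 2e4, seed = 123)
    gt$regret_of(sel) < gt$regret_of(big)
  }, TRUE)
  expect_gte(mean(wins), 0.75)
})

test_that("the brute-force oracle dominates and certifies the OWL fit", {
  # all weight on telehealth subjects: all-telehealth is optimal
  Z <- matrix(rnorm(20), 10, 2)
  A <- rep(c(1, 0), 5)
  w_tel <- ifelse(A == 1, 1, 0)
  or <- brute_force_oracle(Z, A, w_tel)
  expect_equal(or$value, sum(w_tel))

  set.seed(17)
  for (i in 1:10) {
    n <- sample(8:14, 1)
    Z <- matrix(rnorm(n * 2), n)
    A <- rbinom(n, 1, 0.5)
    w <- runif(n, 0, 5)
    or <- brute_force_oracle(Z, A, w)
    expect_lte(or$value, or$best_possible + 1e-12)
    rule <- suppressWarnings(fit_owl(pad6(Z), A, w, 2^-6))
    expect_gte(or$value + 1e-9, weighted_value_01(rule, pad6(Z), A, w))
  }

  expect_error(brute_force_oracle(matrix(0, 20, 2), rep(0:1, 10),
                                  rep(1, 20)), "restricted")
  expect_error(brute_force_oracle(matrix(0, 5, 3), rep(0:1, len = 5),
                                  rep(1, 5)), "restricted")
})

test_that("rules serialize to JSON and back without loss", {
  p <- prepare_analysis(synthetic_config(n = 60), seed = 83)
  rule <- fit_owl(p$ds$Z, p$ds$A, p$w, 1,
                  standardization = p$ds$std_params)
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_json(rule, path, provenance = list(seed = 83, lambda = 1))
  back <- read_rule_json(path)
  expect_equal(back$intercept, rule$intercept, tolerance = 1e-12)
  expect_equal(back$slopes, rule$slopes, tolerance = 1e-12)
  expect_equal(back$standardization$mean, rule$standardization$mean,
               tolerance = 1e-12)
  expect_identical(attr(back, "provenance")$seed, 83L)
})
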
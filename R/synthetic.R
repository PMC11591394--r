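#' Configuration of the synthetic two-arm trial generator
#'
#' Defines a randomized trial emulating a two-modality (telehealth vs.
#' in-person) psychotherapy study: six baseline prescriptive factors, 1:1
#' randomization, a linear outcome model with a treatment-covariate
#' interaction on the 0-80 PCL-5 scale, and covariate-driven (MAR)
#' missingness of the 6-month outcome.
#'
#' The outcome model is
#' \deqn{Y_i = m(z_i) + A_i \tau(z_i) + \varepsilon_i,\qquad
#'       \varepsilon_i \sim N(0, \sigma^2),}
#' clipped to the instrument range \eqn{[0, 80]}, where \eqn{z_i} is the
#' covariate vector standardized by its *population* marginal parameters,
#' \eqn{m} is the in-person (control) mean surface and \eqn{\tau} the
#' telehealth-minus-in-person effect surface, both linear.  Lower outcomes
#' are better, so the true optimal rule assigns telehealth exactly where
#' \eqn{\tau(z) < 0} (ties to telehealth).
#'
#' The outcome of subject \eqn{i} is observed with probability
#' \eqn{\mathrm{expit}(\gamma_0 + \gamma^\top z_i + \gamma_A A_i)}.
#'
#' Default values reproduce the marginal structure of the emulated study:
#' age 42.80 (SD 11.61) truncated to 18-90, prevalences 0.279 (white),
#' 0.639 (disability), 0.344 (rural), 0.492 (low income), baseline symptom
#' score 52.74 (SD 12.81) clipped to 0-80, about 35.25% missing 6-month
#' outcomes, and a marginal 6-month outcome SD close to 21.84.
#'
#' @param n Number of participants (default 122).
#' @param arm_ratio Probability of assignment to telehealth, in (0, 1).
#' @param covariates Named list of marginal parameters: `age_mean`,
#'   `age_sd`, `p_white`, `p_disability`, `p_rural`, `p_low_income`,
#'   `pcl_mean`, `pcl_sd`.
#' @param control_surface Named numeric of length 7 (`intercept` plus the
#'   six factors): in-person mean outcome as a linear function of the
#'   population-standardized covariates, in PCL points.
#' @param interaction_surface Named numeric of length 7: telehealth minus
#'   in-person conditional effect, same parameterization.
#' @param noise_sd Residual outcome SD in PCL points (>= 0).
#' @param missingness Named numeric of length 8 (`intercept`, six factors,
#'   `arm`): logistic coefficients of the *observation* (non-missingness)
#'   model.  An intercept of 20 or more effectively disables missingness.
#' @param seed Default RNG seed used by [simulate_trial()].
#'
#' @return An object of class `synthetic_config`.
#' @seealso [simulate_trial()], [ground_truth()], [regret()]
#' @export
synthetic_config <- function(n = 122,
                             arm_ratio = 0.5,
                             covariates = list(),
                             control_surface = NULL,
                             interaction_surface = NULL,
                             noise_sd = 21,
                             missingness = NULL,
                             seed = 20993L) {
  cov_def <- list(age_mean = 42.80, age_sd = 11.61,
                  p_white = 0.279, p_disability = 0.639,
                  p_rural = 0.344, p_low_income = 0.492,
                  pcl_mean = 52.74, pcl_sd = 12.81)
  unknown <- setdiff(names(covariates), names(cov_def))
  if (length(unknown))
    stop("unknown covariate parameter(s): ", paste(unknown, collapse = ", "))
  cov <- utils::modifyList(cov_def, covariates)

  surf_names <- c("intercept", factor_names())
  ctrl_def <- c(intercept = 30.1, age = 2, white = 0, disability = 2,
                rural = 0, low_income = 2, pcl_baseline = 8)
  # Heterogeneity pattern motivated by access-to-care considerations:
  # telehealth relatively better for rural, disabled and low-income
  # subjects, relatively worse for older and white subjects.
  int_def <- c(intercept = 3.2, age = 4, white = 2, disability = -2,
               rural = -3, low_income = -2, pcl_baseline = 0)
  # Observation-model intercept calibrated by Monte Carlo so the marginal
  # observation rate is 0.6475 (35.25% missing) under the default slopes.
  miss_def <- c(intercept = 0.616, age = -0.4, white = 0, disability = 0,
                rural = 0, low_income = -0.2, pcl_baseline = -0.8,
                arm = 0.2)

  ctrl <- check_surface(control_surface %||% ctrl_def, surf_names,
                        "control_surface")
  inter <- check_surface(interaction_surface %||% int_def, surf_names,
                         "interaction_surface")
  miss <- check_surface(missingness %||% miss_def,
                        c(surf_names, "arm"), "missingness")

  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a single nonnegative count")
  if (length(arm_ratio) != 1 || !is.finite(arm_ratio) ||
      arm_ratio <= 0 || arm_ratio >= 1)
    stop("arm_ratio must lie strictly inside (0, 1)")
  for (p in c("p_white", "p_disability", "p_rural", "p_low_income"))
    if (cov[[p]] < 0 || cov[[p]] > 1)
      stop(p, " must be a probability in [0, 1]")
  if (cov$age_sd < 0 || cov$pcl_sd < 0) stop("marginal SDs must be >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")

  structure(list(n = as.integer(n), arm_ratio = arm_ratio,
                 covariates = cov, control_surface = ctrl,
                 interaction_surface = inter, noise_sd = noise_sd,
                 missingness = miss, seed = as.integer(seed)),
            class = "synthetic_config")
}

check_surface <- function(x, expected, what) {
  x <- unlist(x)
  if (length(x) != length(expected))
    stop(what, " must have entries ", paste(expected, collapse = ", "))
  if (is.null(names(x)) || all(names(x) == "")) {
    names(x) <- expected
  } else if (!setequal(names(x), expected)) {
    stop(what, " must be named with ", paste(expected, collapse = ", "))
  }
  if (any(!is.finite(x))) stop(what, " has non-finite entries")
  x[expected]
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic two-arm trial configuration\n")
  cat(sprintf("  n = %d, P(telehealth) = %.3f, noise SD = %.2f\n",
              x$n, x$arm_ratio, x$noise_sd))
  cat(sprintf("  interaction surface: %s\n",
              paste(sprintf("%s=%.2f", names(x$interaction_surface),
                            x$interaction_surface), collapse = ", ")))
  invisible(x)
}

# Location/scale of a truncated normal chosen so its post-truncation mean
# and SD hit the configured targets (the default age truncation at 18
# shifts a naive truncated draw by ~0.5 years, which would visibly distort
# the marginal).  Closed-form truncated-normal moments, solved by
# Nelder-Mead.
truncnorm_params <- function(mean, sd, lower, upper) {
  if (sd == 0) return(c(mean = mean, sd = 0))
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma; b <- (upper - mu) / sigma
    z <- pnorm(b) - pnorm(a)
    if (z < 1e-12) return(c(NA_real_, NA_real_))
    dm <- (dnorm(a) - dnorm(b)) / z
    m <- mu + sigma * dm
    v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - dm^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(th) {
    mm <- moments(th[1], exp(th[2]))
    if (any(is.na(mm))) return(1e10)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  pa <- pnorm(lower, mean, sd); pb <- pnorm(upper, mean, sd)
  qnorm(pa + runif(n) * (pb - pa), mean, sd)
}

#' Generate baseline covariates
#'
#' Draws the six prescriptive factors on their raw scale: age from a
#' truncated normal on \[18, 90\] (location/scale adjusted so the
#' post-truncation mean and SD equal the configured targets), the four
#' binary indicators from independent Bernoullis, and the baseline symptom
#' score from a normal clipped to \[0, 80\].  Columns are independent.
#'
#' @param config A [synthetic_config()].
#' @param n Number of rows; defaults to `config$n`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A data frame with columns `age`, `white`, `disability`,
#'   `rural`, `low_income`, `pcl_baseline`.
#' @export
generate_covariates <- function(config, n = config$n, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n < 0) stop("n must be nonnegative")
  gen <- function() {
    cv <- config$covariates
    ap <- truncnorm_params(cv$age_mean, cv$age_sd, 18, 90)
    age <- rtruncnorm(n, ap["mean"], ap["sd"], 18, 90)
    white <- rbinom(n, 1, cv$p_white)
    disability <- rbinom(n, 1, cv$p_disability)
    rural <- rbinom(n, 1, cv$p_rural)
    low_income <- rbinom(n, 1, cv$p_low_income)
    pcl <- pmin(80, pmax(0, rnorm(n, cv$pcl_mean, cv$pcl_sd)))
    data.frame(age = age, white = white, disability = disability,
               rural = rural, low_income = low_income, pcl_baseline = pcl)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Randomize arm assignments
#'
#' @param n Number of participants.
#' @param arm_ratio Probability of telehealth assignment, in (0, 1).
#' @param seed Optional seed.
#' @return Integer vector of 1 (telehealth) / 0 (in-person).
#' @export
randomize_arms <- function(n, arm_ratio = 0.5, seed = NULL) {
  if (n < 0) stop("n must be nonnegative")
  if (length(arm_ratio) != 1 || !is.finite(arm_ratio) ||
      arm_ratio <= 0 || arm_ratio >= 1)
    stop("arm_ratio must lie strictly inside (0, 1)")
  gen <- function() rbinom(n, 1, arm_ratio)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Standardize raw covariates by the *configured population* marginals
# (continuous: (x - mu)/sigma; binary: (x - p)/sqrt(p(1-p))).  This is the
# scale on which the generator's outcome surfaces are parameterized; the
# analysis side standardizes by sample moments instead.
population_standardize <- function(covariates, config) {
  cv <- config$covariates
  sdb <- function(p) if (p <= 0 || p >= 1) 1 else sqrt(p * (1 - p))
  cbind(age = (covariates$age - cv$age_mean) / max(cv$age_sd, 1e-12),
        white = (covariates$white - cv$p_white) / sdb(cv$p_white),
        disability = (covariates$disability - cv$p_disability) /
          sdb(cv$p_disability),
        rural = (covariates$rural - cv$p_rural) / sdb(cv$p_rural),
        low_income = (covariates$low_income - cv$p_low_income) /
          sdb(cv$p_low_income),
        pcl_baseline = (covariates$pcl_baseline - cv$pcl_mean) /
          max(cv$pcl_sd, 1e-12))
}

eval_surface <- function(surface, Z) {
  drop(surface["intercept"] + Z %*% surface[factor_names()])
}

#' Generate 6-month outcomes
#'
#' Applies the configured linear control and interaction surfaces to the
#' population-standardized covariates, adds Gaussian noise and clips to the
#' instrument range \[0, 80\].
#'
#' @param covariates Raw covariate data frame from [generate_covariates()].
#' @param arms Arm vector (1 = telehealth, 0 = in-person).
#' @param config A [synthetic_config()].
#' @param seed Optional seed.
#' @return Numeric outcome vector in \[0, 80\].
#' @export
generate_outcomes <- function(covariates, arms, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(covariates) != length(arms))
    stop("covariates and arms must have equal length")
  Z <- population_standardize(covariates, config)
  mu <- eval_surface(config$control_surface, Z) +
    arms * eval_surface(config$interaction_surface, Z)
  gen <- function() pmin(80, pmax(0, mu + rnorm(length(arms), 0,
                                                config$noise_sd)))
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Impose covariate-driven outcome missingness
#'
#' Each outcome is independently retained with probability
#' `expit(gamma_0 + gamma' z + gamma_A A)` under the configured logistic
#' observation model (missing at random given covariates and arm).
#'
#' @inheritParams generate_outcomes
#' @param outcomes Complete outcome vector.
#' @return A list with `outcome` (masked vector, `NA` = missing),
#'   `observed` (logical mask) and `prob` (true observation
#'   probabilities).
#' @export
impose_missingness <- function(outcomes, covariates, arms, config,
                               seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- length(outcomes)
  if (nrow(covariates) != n || length(arms) != n)
    stop("outcomes, covariates and arms must have equal length")
  Z <- population_standardize(covariates, config)
  g <- config$missingness
  prob <- plogis(g["intercept"] + drop(Z %*% g[factor_names()]) +
                   g["arm"] * arms)
  gen <- function() as.logical(rbinom(n, 1, prob))
  observed <- if (is.null(seed)) gen() else with_seed(seed, gen())
  out <- outcomes
  out[!observed] <- NA_real_
  list(outcome = out, observed = observed, prob = unname(prob))
}

#' Simulate a complete synthetic trial
#'
#' Runs covariate generation, randomization, outcome generation and
#' missingness imposition with per-stage child seeds derived from `seed`
#' (see [derive_seed()]); the result is bit-identical across runs with the
#' same configuration and seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Run seed; defaults to `config$seed`.
#' @return A data frame in the canonical trial layout
#'   ([trial_csv_columns()]), with attributes `observed_prob` (true
#'   observation probabilities) and `seed`.
#' @export
simulate_trial <- function(config = synthetic_config(),
                           seed = config$seed) {
  covs <- generate_covariates(config, seed = derive_seed(seed, "covariates"))
  arms <- randomize_arms(config$n, config$arm_ratio,
                         seed = derive_seed(seed, "arms"))
  y <- generate_outcomes(covs, arms, config,
                         seed = derive_seed(seed, "outcomes"))
  miss <- impose_missingness(y, covs, arms, config,
                             seed = derive_seed(seed, "missingness"))
  out <- cbind(data.frame(id = seq_len(config$n)), covs,
               data.frame(arm = arms, pcl_6month = miss$outcome))
  attr(out, "observed_prob") <- miss$prob
  attr(out, "seed") <- seed
  out
}

# Mean of clip(X, lo, hi) for X ~ N(mu, sd): censored-normal closed form.
clipnorm_mean <- function(mu, sd, lo = 0, hi = 80) {
  if (sd == 0) return(pmin(hi, pmax(lo, mu)))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) + (lo - mu) * pnorm(a) +
    (hi - mu) * (1 - pnorm(b))
}

#' Ground truth of a synthetic configuration
#'
#' Computes the generator's true optimal rule and the expected outcomes
#' (with noise and clipping accounted for in closed form, covariates
#' integrated by Monte Carlo) under the optimal rule and under each
#' one-size-fits-all policy.
#'
#' @param config A [synthetic_config()].
#' @param n_mc Monte-Carlo draws for the covariate integral.
#' @param seed Seed for the covariate draws (default derived from
#'   `config$seed`).
#' @return A list of class `synthetic_truth` with elements `true_rule`
#'   (a [decision_rule()] on the population-standardized scale),
#'   `optimal_value`, `arm_values` (named: telehealth, in_person) and
#'   `regret_of(rule)`, a function computing the noise-free regret of any
#'   rule on the same covariate draw.
#' @export
ground_truth <- function(config, n_mc = 1e5,
                         seed = derive_seed(config$seed, "truth")) {
  stopifnot(inherits(config, "synthetic_config"))
  tau <- config$interaction_surface
  true_rule <- decision_rule(
    intercept = -tau[["intercept"]],
    slopes = -tau[factor_names()],
    standardization = population_standardization_params(config))

  covs <- generate_covariates(config, n = n_mc, seed = seed)
  Z <- population_standardize(covs, config)
  m0 <- eval_surface(config$control_surface, Z)
  m1 <- m0 + eval_surface(config$interaction_surface, Z)
  v0 <- clipnorm_mean(m0, config$noise_sd)
  v1 <- clipnorm_mean(m1, config$noise_sd)
  arm_values <- c(telehealth = mean(v1), in_person = mean(v0))
  d_opt <- as.numeric(m1 <= m0)
  optimal_value <- mean(ifelse(d_opt == 1, v1, v0))

  # Noise-free surfaces, clipped to the instrument range; used for regret.
  s0 <- pmin(80, pmax(0, m0))
  s1 <- pmin(80, pmax(0, m1))
  opt_nf <- mean(pmin(s0, s1))
  regret_of <- function(rule) {
    d <- rule_assignments(rule, covs)
    mean(ifelse(d == 1, s1, s0)) - opt_nf
  }

  structure(list(true_rule = true_rule, optimal_value = optimal_value,
                 arm_values = arm_values, regret_of = regret_of,
                 n_mc = n_mc),
            class = "synthetic_truth")
}

population_standardization_params <- function(config) {
  cv <- config$covariates
  sdb <- function(p) if (p <= 0 || p >= 1) 1 else sqrt(p * (1 - p))
  list(mean = c(age = cv$age_mean, white = cv$p_white,
                disability = cv$p_disability, rural = cv$p_rural,
                low_income = cv$p_low_income, pcl_baseline = cv$pcl_mean),
       sd = c(age = cv$age_sd, white = sdb(cv$p_white),
              disability = sdb(cv$p_disability), rural = sdb(cv$p_rural),
              low_income = sdb(cv$p_low_income), pcl_baseline = cv$pcl_sd))
}

# Assignments of a rule on raw covariates, through the rule's own embedded
# standardization (population scale for generator truth, training-sample
# scale for fitted rules).
rule_assignments <- function(rule, covariates) {
  Z <- if (is.null(rule$standardization)) {
    as.matrix(covariates[, factor_names()])
  } else {
    apply_standardization(rule$standardization,
                          as.matrix(covariates[, factor_names()]))
  }
  apply_rule(rule, Z)$assignment
}

#' Noise-free regret of a decision rule
#'
#' Monte-Carlo estimate of the expected-outcome gap between a candidate
#' rule and the generator's true optimal rule, on the noise-free (clipped)
#' outcome surfaces.  Nonnegative up to Monte-Carlo error for every rule;
#' exactly zero for the true rule.
#'
#' @param rule A [decision_rule()] carrying its own standardization.
#' @param config A [synthetic_config()].
#' @param n_mc Monte-Carlo draws (a warning is raised below 1000, where
#'   the estimate is unstable).
#' @param seed Seed for the covariate draws.
#' @return Expected PCL-point gap (scalar).
#' @export
regret <- function(rule, config, n_mc = 1e5,
                   seed = derive_seed(config$seed, "truth")) {
  if (n_mc < 1000)
    warning("regret estimate with n_mc < 1000 is unstable")
  truth <- ground_truth(config, n_mc = n_mc, seed = seed)
  truth$regret_of(rule)
}

#' True value of a rule under the generator (with outcome noise)
#'
#' Expected observed outcome if the whole population were treated by
#' `rule`: the censored-normal mean of the outcome model (noise and
#' clipping in closed form), integrated over covariates by Monte Carlo.
#' This is the estimand of [estimate_value()].
#'
#' @inheritParams regret
#' @return Expected outcome in PCL points.
#' @export
true_policy_value <- function(rule, config, n_mc = 1e5,
                              seed = derive_seed(config$seed, "truth")) {
  covs <- generate_covariates(config, n = n_mc, seed = seed)
  Z <- population_standardize(covs, config)
  m0 <- eval_surface(config$control_surface, Z)
  m1 <- m0 + eval_surface(config$interaction_surface, Z)
  d <- rule_assignments(rule, covs)
  mean(clipnorm_mean(ifelse(d == 1, m1, m0), config$noise_sd))
}

#' True marginal outcome mean under randomization
#'
#' Expected observed outcome of the trial population (arms mixed at the
#' configured randomization ratio), the target of the missing-data
#' correction diagnostics.
#'
#' @inheritParams regret
#' @return Expected outcome in PCL points.
#' @export
true_outcome_mean <- function(config, n_mc = 1e5,
                              seed = derive_seed(config$seed, "truth")) {
  covs <- generate_covariates(config, n = n_mc, seed = seed)
  Z <- population_standardize(covs, config)
  m0 <- eval_surface(config$control_surface, Z)
  m1 <- m0 + eval_surface(config$interaction_surface, Z)
  mean((1 - config$arm_ratio) * clipnorm_mean(m0, config$noise_sd) +
         config$arm_ratio * clipnorm_mean(m1, config$noise_sd))
}

#' Write / read a trial in the canonical CSV layout
#'
#' `write_trial_csv()` writes the exact header
#' `id,age,white,disability,rural,low_income,pcl_baseline,arm,pcl_6month`
#' with empty fields for missing outcomes; `read_trial_csv()` reads it
#' back, mapping empty fields to `NA`.
#'
#' @param trial Data frame in the layout of [simulate_trial()].
#' @param path File path.
#' @return `read_trial_csv()` returns the data frame;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  cols <- trial_csv_columns()
  missing_cols <- setdiff(cols, names(trial))
  if (length(missing_cols))
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  write.csv(trial[, cols, drop = FALSE], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(trial_csv_columns(), "id"), names(df))
  if (length(missing_cols))
    stop("trial CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Serialize generator ground truth to JSON
#'
#' @param config A [synthetic_config()].
#' @param path Output path (conventionally `truth.json`).
#' @param n_mc Monte-Carlo draws for the value integrals.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(config, path, n_mc = 1e5) {
  truth <- ground_truth(config, n_mc = n_mc)
  payload <- list(
    control_surface = as.list(config$control_surface),
    interaction_surface = as.list(config$interaction_surface),
    noise_sd = config$noise_sd,
    missingness = as.list(config$missingness),
    true_rule = rule_to_list(truth$true_rule),
    optimal_value = truth$optimal_value,
    arm_values = as.list(truth$arm_values),
    n_mc = n_mc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
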
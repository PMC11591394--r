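#' Hajek inverse-probability estimate of a rule's value
#'
#' Estimates the mean outcome if everyone were treated by `rule`:
#' \deqn{\hat V(d) = \frac{\sum_i r_i Y_i 1\{A_i = d(z_i)\} / \pi_i}
#'                        {\sum_i r_i 1\{A_i = d(z_i)\} / \pi_i},}
#' summing over subjects with observed outcomes, where \eqn{r_i} are the
#' observation weights and \eqn{\pi_i} the propensity of the arm actually
#' received.  The normalization (Hajek rather than Horvitz-Thompson)
#' makes the estimate invariant to outcome location shifts; with all
#' outcomes observed and a fixed-arm rule it reduces exactly to that
#' arm's sample mean.
#'
#' @param rule A [decision_rule()].
#' @param dataset A `trial_dataset`.
#' @param r An [observation_weights()] object or weight vector (0 for
#'   missing outcomes); `NULL` treats all observed subjects as weight 1.
#' @param propensities As in [owl_weights()]; `NULL` uses empirical arm
#'   frequencies.
#' @return The estimated value in PCL points, with the number of matched
#'   subjects in attribute `"n_matched"`.
#' @export
estimate_value <- function(rule, dataset, r = NULL, propensities = NULL) {
  stopifnot(inherits(rule, "decision_rule"),
            inherits(dataset, "trial_dataset"))
  rv <- if (is.null(r)) as.numeric(dataset$observed)
  else if (inherits(r, "observation_weights")) r$weights
  else as.numeric(r)
  pi_i <- propensity_of_received(dataset$A, propensities)
  d <- apply_rule(rule, dataset$Z)$assignment
  use <- dataset$observed & dataset$A == d & rv > 0
  if (!any(use))
    stop("no observed subject matches the rule's assignment; ",
         "the value is undefined")
  v <- sum(rv[use] * dataset$Y[use] / pi_i[use]) / sum(rv[use] / pi_i[use])
  attr(v, "n_matched") <- sum(use)
  v
}

#' Contrast the values of two rules on the same data
#'
#' @param rule_a,rule_b [decision_rule()] objects.
#' @inheritParams estimate_value
#' @return `V(rule_a) - V(rule_b)` in PCL points (negative favors
#'   `rule_a` since lower outcomes are better).
#' @export
contrast_values <- function(rule_a, rule_b, dataset, r = NULL,
                            propensities = NULL) {
  as.numeric(estimate_value(rule_a, dataset, r, propensities)) -
    as.numeric(estimate_value(rule_b, dataset, r, propensities))
}

#' Bootstrap standard errors and Wald confidence intervals
#'
#' Resamples the trial with replacement, stratified by arm (conditioning
#' on the realized randomization ratio), and recomputes the statistic on
#' every replicate.  The statistic receives a `trial_dataset` and should
#' re-estimate whatever it needs internally (typically the observation
#' model and weights, with the decision rule held fixed).  The SE is the
#' SD of the replicate statistics and the 95% CI the Wald interval
#' `estimate +/- 1.96 * SE`.  Replicates on which the statistic errors
#' are dropped (with a warning); more than 10% failures is an error.
#'
#' @param statistic Function `trial_dataset -> numeric` (scalar or named
#'   vector).
#' @param dataset A `trial_dataset`.
#' @param B Number of replicates (>= 2); 1000 by default.
#' @param seed RNG seed; fixed seed gives bit-identical (SE, CI).
#' @return Object of class `boot_inference`: list with `estimate`, `se`,
#'   `ci_lower`, `ci_upper` (aligned vectors), `B`, `n_failed`,
#'   `replicates` (kept replicate statistics, one row each).
#' @export
bootstrap_inference <- function(statistic, dataset, B = 1000, seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"), B >= 2)
  est <- statistic(dataset)
  idx_tele <- which(dataset$A == 1)
  idx_inp <- which(dataset$A == 0)

  reps <- with_seed(derive_seed(seed, "bootstrap"), {
    lapply(seq_len(B), function(b) {
      idx <- c(sample(idx_tele, length(idx_tele), replace = TRUE),
               sample(idx_inp, length(idx_inp), replace = TRUE))
      try(statistic(subset_dataset(dataset, idx)), silent = TRUE)
    })
  })

  failed <- vapply(reps, inherits, TRUE, what = "try-error")
  if (mean(failed) > 0.10)
    stop("the statistic failed on ", sum(failed), " of ", B,
         " bootstrap replicates (> 10%)")
  if (any(failed))
    warning(sum(failed), " failed bootstrap replicate(s) dropped")
  mat <- do.call(rbind, lapply(reps[!failed], function(x)
    unlist(x, use.names = TRUE)))
  se <- apply(mat, 2, sd)
  est_v <- unlist(est, use.names = TRUE)
  structure(list(estimate = est_v, se = se,
                 ci_lower = est_v - 1.96 * se,
                 ci_upper = est_v + 1.96 * se,
                 B = B, n_failed = sum(failed), replicates = mat),
            class = "boot_inference")
}

#' @export
print.boot_inference <- function(x, ...) {
  out <- data.frame(estimate = round(x$estimate, 2),
                    se = round(x$se, 3),
                    ci = sprintf("(%.2f, %.2f)", x$ci_lower, x$ci_upper))
  print(out)
  cat(sprintf("bootstrap replicates: %d kept, %d failed\n",
              x$B - x$n_failed, x$n_failed))
  invisible(x)
}

#' Performance table for a fitted rule
#'
#' The headline analysis: the estimated value under the fitted rule, its
#' contrasts against the two one-size-fits-all rules, bootstrap standard
#' errors with Wald 95% intervals, and the counts of subjects the rule
#' assigns to each arm.  The rule is held fixed across bootstrap
#' replicates while the observation model, weights and values are
#' re-estimated.
#'
#' When cross-validated (held-out) assignments are supplied -- as
#' produced by [select_lambda()] at the selected penalty -- the rule's
#' value is computed from them, so it estimates out-of-sample performance
#' rather than the optimistic in-sample value; each subject's assignment
#' then comes from a fit that excluded them, and the assignment vector
#' (not the rule) is what the bootstrap holds fixed.  The fixed-arm
#' comparator values carry no overfitting and are always in-sample.
#'
#' @param dataset A `trial_dataset`.
#' @param rule The fitted [decision_rule()].
#' @param B Bootstrap replicates.
#' @param clip_floor Observation-probability floor for the weights.
#' @param propensities As in [owl_weights()].
#' @param cv_assignments Optional held-out assignment vector (length n,
#'   `NA` allowed) used for the rule's value.
#' @param seed Bootstrap seed.
#' @return Object of class `performance_table`: a data frame with rows
#'   `V_dopt`, `V_dopt - V_telehealth`, `V_dopt - V_inperson` (estimate,
#'   se, ci_lower, ci_upper, formatted) and `n_assigned_telehealth`,
#'   `n_assigned_inperson` (counts, no interval).
#' @export
performance_table <- function(dataset, rule, B = 1000, clip_floor = 0.05,
                              propensities = NULL, cv_assignments = NULL,
                              seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  d_opt <- if (is.null(cv_assignments))
    apply_rule(rule, dataset$Z)$assignment
  else {
    stopifnot(length(cv_assignments) == dataset$n)
    as.integer(cv_assignments)
  }
  key <- paste0("k", seq_len(dataset$n))   # align assignments on resample
  names(d_opt) <- key
  statistic <- function(ds) {
    m <- fit_observation_model(ds)
    r <- observation_weights(m, ds, clip_floor = clip_floor)
    v_opt <- hajek_value(ds, d_opt[ds$ids], r, propensities)
    v_tel <- as.numeric(estimate_value(fixed_rule("telehealth"), ds, r,
                                       propensities))
    v_inp <- as.numeric(estimate_value(fixed_rule("in_person"), ds, r,
                                       propensities))
    c(v_dopt = v_opt, diff_telehealth = v_opt - v_tel,
      diff_inperson = v_opt - v_inp)
  }
  ds0 <- dataset
  ds0$ids <- key
  boot <- bootstrap_inference(statistic, ds0, B = B, seed = seed)
  d <- apply_rule(rule, dataset$Z)$assignment

  values <- data.frame(
    parameter = c("V_dopt", "V_dopt - V_telehealth", "V_dopt - V_inperson"),
    estimate = as.numeric(boot$estimate),
    se = as.numeric(boot$se),
    ci_lower = as.numeric(boot$ci_lower),
    ci_upper = as.numeric(boot$ci_upper))
  values$formatted <- sprintf("%.2f (%.2f, %.2f)", values$estimate,
                              values$ci_lower, values$ci_upper)
  counts <- data.frame(
    parameter = c("n_assigned_telehealth", "n_assigned_inperson"),
    estimate = c(sum(d == 1), sum(d == 0)),
    se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    formatted = as.character(c(sum(d == 1), sum(d == 0))))
  out <- rbind(values, counts)
  attr(out, "boot") <- boot
  class(out) <- c("performance_table", "data.frame")
  out
}

#' @export
print.performance_table <- function(x, ...) {
  cat("Performance of the individualized treatment rule",
      "(PCL points, lower = better)\n")
  print(data.frame(parameter = x$parameter,
                   `estimate (95% CI)` = x$formatted,
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}
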
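#' Fit the logistic observation (non-missingness) model
#'
#' Models the probability that the 6-month outcome is observed as a
#' logistic function of the six standardized prescriptive factors plus the
#' treatment arm (main effects only), by maximum likelihood.  Degenerate
#' samples (all observed or all missing) yield a constant-probability
#' model; quasi-separation triggers a fallback to a ridge-regularized fit
#' with a warning.
#'
#' @param dataset A [assemble_analysis_dataset()] result.
#' @param ridge_lambda Penalty used by the separation fallback.
#' @return Object of class `observation_model`: list with `coefficients`
#'   (intercept, six factors, arm), `se` (ML standard errors, `NA` for
#'   fallback fits), `method` (`"ml"`, `"ridge"` or `"constant"`),
#'   `converged`, and `prob` for constant models.
#' @export
fit_observation_model <- function(dataset, ridge_lambda = 0.01) {
  stopifnot(inherits(dataset, "trial_dataset"))
  R <- as.integer(dataset$observed)
  X <- cbind(dataset$Z, arm = dataset$A)
  coef_names <- c("intercept", colnames(dataset$Z), "arm")

  if (all(R == 1) || all(R == 0)) {
    cf <- c(if (all(R == 1)) 36 else -36, rep(0, ncol(X)))
    names(cf) <- coef_names
    return(structure(list(coefficients = cf, se = NULL,
                          method = "constant", converged = TRUE,
                          prob = mean(R)),
                     class = "observation_model"))
  }

  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit2 <- glm(R ~ X, family = binomial(),
                    control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })

  if (separated || !fit$converged) {
    warning("observation model is (quasi-)separated; ",
            "falling back to a ridge-regularized fit")
    rf <- glmnet::glmnet(X, R, family = "binomial", alpha = 0,
                         lambda = ridge_lambda, standardize = FALSE)
    cf <- as.numeric(coef(rf))
    names(cf) <- coef_names
    return(structure(list(coefficients = cf, se = NULL, method = "ridge",
                          converged = TRUE, prob = NULL),
                     class = "observation_model"))
  }

  cf <- coef(fit)
  se <- sqrt(diag(vcov_safe(fit)))
  names(cf) <- names(se) <- coef_names
  structure(list(coefficients = cf, se = se, method = "ml",
                 converged = fit$converged, prob = NULL),
            class = "observation_model")
}

vcov_safe <- function(fit) {
  v <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(v, "try-error")) {
    p <- length(coef(fit))
    matrix(NA_real_, p, p)
  } else v
}

#' @export
print.observation_model <- function(x, ...) {
  cat("Observation (non-missingness) model [", x$method, "]\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Inverse-probability-of-observation weights
#'
#' Computes fitted observation probabilities from an
#' [fit_observation_model()] fit, floors them at `clip_floor` (a
#' positivity safeguard bounding the weight variance), and returns
#' weights `r_i = 1 / p_i` for subjects with an observed outcome and 0
#' for subjects with a missing outcome.
#'
#' @param model An `observation_model`.
#' @param dataset The `trial_dataset` the weights are for.
#' @param clip_floor Probability floor in (0, 0.5]; default 0.05.
#' @return Object of class `observation_weights`: list with `prob`
#'   (fitted, pre-floor), `prob_clipped`, `weights`, `n_clipped`,
#'   `clip_floor`, `model`.
#' @export
observation_weights <- function(model, dataset, clip_floor = 0.05) {
  stopifnot(inherits(model, "observation_model"),
            inherits(dataset, "trial_dataset"))
  if (length(clip_floor) != 1 || !is.finite(clip_floor) ||
      clip_floor <= 0 || clip_floor > 0.5)
    stop("clip_floor must lie in (0, 0.5]")
  X <- cbind(1, dataset$Z, arm = dataset$A)
  if (ncol(X) != length(model$coefficients))
    stop("model coefficients are not conformable with the design matrix")
  p <- drop(plogis(X %*% model$coefficients))
  pc <- pmax(p, clip_floor)
  n_clipped <- sum(p < clip_floor)
  if (n_clipped > 0)
    message(n_clipped, " observation probabilit",
            if (n_clipped == 1) "y" else "ies",
            " floored at ", clip_floor)
  r <- ifelse(dataset$observed, 1 / pc, 0)
  structure(list(prob = p, prob_clipped = pc, weights = r,
                 n_clipped = n_clipped, clip_floor = clip_floor,
                 model = model),
            class = "observation_weights")
}

#' @export
print.observation_weights <- function(x, ...) {
  pos <- x$weights[x$weights > 0]
  cat(sprintf(
    "Observation weights: %d observed (range %.2f-%.2f), %d zeroed (missing), %d floored\n",
    length(pos), min(pos), max(pos), sum(x$weights == 0), x$n_clipped))
  invisible(x)
}
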
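#' Linear decision rules
#'
#' A decision rule scores a standardized covariate row as
#' `intercept + slopes' z` and assigns telehealth (1) when the score is
#' nonnegative, in-person (0) otherwise; the tie at score exactly 0 goes
#' to telehealth by the indicator convention `I(score >= 0)`.
#'
#' @param intercept Decision-score offset.
#' @param slopes Numeric vector of six coefficients in the fixed factor
#'   order (`age`, `white`, `disability`, `rural`, `low_income`,
#'   `pcl_baseline`).
#' @param standardization Optional list (`mean`, `sd`) mapping raw
#'   covariates to the scale the coefficients act on; embedded so a saved
#'   rule is self-contained for scoring future individuals.
#' @param tie Assignment at score 0; only `"telehealth"` is supported.
#' @return Object of class `decision_rule`.
#' @export
decision_rule <- function(intercept, slopes, standardization = NULL,
                          tie = "telehealth") {
  if (length(slopes) != length(factor_names()))
    stop("a decision rule has exactly ", length(factor_names()), " slopes")
  if (!identical(tie, "telehealth"))
    stop("the tie at score 0 is fixed to telehealth")
  slopes <- as.numeric(slopes)
  names(slopes) <- factor_names()
  structure(list(intercept = as.numeric(intercept), slopes = slopes,
                 standardization = standardization, tie = tie),
            class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Score covariates and assign treatment under a rule
#'
#' @param rule A [decision_rule()].
#' @param z A standardized covariate row (length 6) or an n x 6 matrix.
#' @return List with `score` and `assignment` (1 = telehealth,
#'   0 = in-person), vectorized over rows.
#' @export
apply_rule <- function(rule, z) {
  stopifnot(inherits(rule, "decision_rule"))
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(Z) != length(rule$slopes))
    stop("covariate row has ", ncol(Z), " entries; expected ",
         length(rule$slopes))
  score <- drop(rule$intercept + Z %*% rule$slopes)
  list(score = score, assignment = as.integer(score >= 0))
}

#' Score future individuals on the raw covariate scale
#'
#' Applies the rule's embedded standardization to raw covariate values
#' and then scores them, so a deserialized rule can be used directly on
#' new measurements.  Rules without embedded standardization expect
#' already-standardized input.
#'
#' @param object A [decision_rule()].
#' @param newdata Raw covariate row (length 6, fixed factor order) or an
#'   n x 6 matrix / data frame.
#' @param ... Unused.
#' @return As [apply_rule()]: list with `score` and `assignment`.
#' @export
predict.decision_rule <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) as.matrix(newdata[, factor_names()])
  else newdata
  z <- if (is.null(object$standardization)) X
  else apply_standardization(object$standardization, X)
  apply_rule(object, z)
}

#' One-size-fits-all rules
#'
#' @param arm `"telehealth"` or `"in_person"`.
#' @return A [decision_rule()] with zero slopes and intercept +1
#'   (telehealth) or -1 (in-person), assigning every subject to that arm.
#' @export
fixed_rule <- function(arm = c("telehealth", "in_person")) {
  arm <- match.arg(arm)
  decision_rule(intercept = if (arm == "telehealth") 1 else -1,
                slopes = rep(0, length(factor_names())))
}

#' Reward transform of the outcome
#'
#' Maps the 0-80 symptom score to the nonnegative reward `B = 80 - Y`
#' (larger = better), anchored at the instrument's printed maximum, so
#' that value maximization in the weighted classification corresponds to
#' symptom minimization.  `NA` outcomes (missing) propagate.
#'
#' @param Y Outcome vector; observed values must lie in \[0, 80\].
#' @return Reward vector.
#' @export
compute_rewards <- function(Y) {
  obs <- !is.na(Y)
  if (any(Y[obs] < 0 | Y[obs] > 80))
    stop("outcomes must lie in [0, 80]")
  80 - Y
}

#' Subject weights for Outcome Weighted Learning
#'
#' Combines the reward, the inverse-probability-of-observation weight and
#' the propensity of the arm actually received:
#' `w_i = B_i * r_i / pi_i`, with `w_i = 0` exactly for missing outcomes.
#'
#' @param B Reward vector from [compute_rewards()].
#' @param r An [observation_weights()] object or a bare weight vector
#'   (0 for missing outcomes).
#' @param A Arm vector (1 = telehealth, 0 = in-person).
#' @param propensities Either a single probability `P(A = 1)` or a vector
#'   of per-subject probabilities of the arm actually received.  `NULL`
#'   (default) uses the empirical arm frequencies.
#' @return Object of class `owl_weights`: list with `w`, `reward`,
#'   `obs_weight`, `propensity`.
#' @export
owl_weights <- function(B, r, A, propensities = NULL) {
  rv <- if (inherits(r, "observation_weights")) r$weights else as.numeric(r)
  n <- length(A)
  stopifnot(length(B) == n, length(rv) == n)
  pi_i <- propensity_of_received(A, propensities)
  if (any(pi_i <= 0 | pi_i >= 1))
    stop("propensities must lie strictly inside (0, 1) (positivity)")
  w <- ifelse(rv == 0, 0, B * rv / pi_i)
  if (anyNA(w))
    stop("rewards are missing for subjects with positive observation weight")
  if (any(w < 0)) stop("OWL weights must be nonnegative")
  structure(list(w = w, reward = B, obs_weight = rv, propensity = pi_i),
            class = "owl_weights")
}

# Probability of the arm actually received, from a scalar P(A = 1), a
# per-subject vector, or (default) the empirical arm frequencies.
propensity_of_received <- function(A, propensities = NULL) {
  if (is.null(propensities)) {
    p1 <- mean(A == 1)
    if (p1 <= 0 || p1 >= 1)
      stop("both arms must be present to form empirical propensities")
    ifelse(A == 1, p1, 1 - p1)
  } else if (length(propensities) == 1) {
    ifelse(A == 1, propensities, 1 - propensities)
  } else {
    stopifnot(length(propensities) == length(A))
    as.numeric(propensities)
  }
}

#' Default ridge-penalty grid
#'
#' Thirteen log-spaced candidates, `2^-8` through `2^4`, in units of the
#' mean positive OWL weight (see [select_lambda()]): after that scaling
#' the grid spans near-unregularized fits through collapse to a
#' fixed-arm rule irrespective of the outcome scale.
#'
#' @return Numeric vector.
#' @export
default_lambda_grid <- function() 2^seq(-8, 4)

#' Fit the OWL decision rule at a fixed penalty
#'
#' Minimizes the weighted hinge loss with ridge penalty
#' \deqn{\frac1n \sum_i w_i \max\{0, 1 - a_i(\beta_0 + \beta^\top z_i)\}
#'       + \lambda \|\beta\|^2,}
#' where \eqn{a_i = +1} for telehealth and \eqn{-1} for in-person and the
#' intercept is unpenalized.  Solved exactly as a convex program: the
#' equivalent weighted support-vector-machine dual by a deterministic SMO
#' algorithm (compiled), then the intercept by exact minimization of the
#' piecewise-linear profile over its breakpoints.
#'
#' @param Z Standardized covariate matrix (n x 6).
#' @param A Arm vector (1 = telehealth, 0 = in-person).
#' @param w An [owl_weights()] object or a nonnegative weight vector.
#' @param lambda Ridge penalty (>= 0; 0 is run with a large finite box
#'   bound in the dual).
#' @param standardization Optional parameters embedded in the returned
#'   rule.
#' @param eps KKT (maximal pair violation) tolerance of the dual solver.
#' @param gap_tol Relative duality-gap tolerance; the solver also stops
#'   once the certified primal-dual gap falls below this fraction of the
#'   objective, which governs on ill-conditioned instances where the
#'   absolute pair violation stalls far above `eps` at a numerically
#'   optimal iterate.
#' @param max_iter Dual iteration cap; exceeding it without a certified
#'   near-optimal gap is an error carrying the solver status.
#' @return A [decision_rule()] with attributes `objective` (attained
#'   primal value), `duality_gap` (on the objective scale), `kkt_gap`,
#'   `iterations` and `lambda`.  If every weight is zero the zero rule is
#'   returned with a warning (all subjects then go to telehealth by the
#'   tie convention).
#' @export
fit_owl <- function(Z, A, w, lambda, standardization = NULL,
                    eps = 1e-7, gap_tol = 1e-6, max_iter = 5e6) {
  Z <- as.matrix(Z)
  wv <- if (inherits(w, "owl_weights")) w$w else as.numeric(w)
  n <- nrow(Z)
  stopifnot(length(A) == n, length(wv) == n)
  if (any(wv < 0) || anyNA(wv)) stop("weights must be nonnegative")
  if (lambda < 0) stop("lambda must be >= 0")
  a <- ifelse(A == 1, 1, -1)

  zero_rule <- function() {
    rule <- decision_rule(0, rep(0, ncol(Z)), standardization)
    attr(rule, "objective") <- 0
    attr(rule, "duality_gap") <- 0
    attr(rule, "kkt_gap") <- 0
    attr(rule, "iterations") <- 0L
    attr(rule, "lambda") <- lambda
    rule
  }
  if (all(wv == 0)) {
    warning("all OWL weights are zero; returning the zero rule")
    return(zero_rule())
  }

  Cvec <- if (lambda == 0) ifelse(wv > 0, 1e8, 0) else wv / (2 * n * lambda)
  sol <- smo_weighted_svm(Z, a, Cvec, eps, as.integer(max_iter),
                          gap_tol = gap_tol, lam2 = 2 * lambda)

  beta <- drop(sol$beta)
  f <- drop(Z %*% beta)
  b0 <- optimal_intercept(f, a, wv)

  primal_svm <- 0.5 * sum(beta^2) + sum(Cvec * pmax(0, 1 - a * (b0 + f)))
  objective <- mean(wv * pmax(0, 1 - a * (b0 + f))) + lambda * sum(beta^2)
  gap <- if (lambda == 0) NA_real_
  else 2 * lambda * (primal_svm - sol$dual_objective)

  if (!sol$converged) {
    rel_gap <- gap / (1 + abs(objective))
    if (is.na(rel_gap) || rel_gap > 100 * gap_tol)
      stop(sprintf(
        "OWL dual solver did not converge in %d iterations (KKT gap %.3g, duality gap %.3g)",
        sol$iterations, sol$kkt_gap, gap))
    warning(sprintf(
      "OWL dual solver stopped at the iteration cap with relative duality gap %.3g",
      rel_gap))
  }

  rule <- decision_rule(b0, beta, standardization)
  attr(rule, "objective") <- objective
  attr(rule, "duality_gap") <- gap
  attr(rule, "kkt_gap") <- sol$kkt_gap
  attr(rule, "iterations") <- sol$iterations
  attr(rule, "lambda") <- lambda
  rule
}

# Exact minimizer of the piecewise-linear intercept profile
# h(b) = sum_i w_i max(0, 1 - a_i (f_i + b)).  A convex piecewise-linear
# function attains its minimum at a breakpoint b = a_i - f_i; ties (a flat
# optimal segment) resolve to the midpoint of the extreme optimal
# breakpoints, which keeps the fit deterministic.
optimal_intercept <- function(f, a, w) {
  keep <- w > 0
  cand <- sort(unique(a[keep] - f[keep]))
  if (!length(cand)) return(0)
  h <- vapply(cand, function(b) sum(w * pmax(0, 1 - a * (f + b))), 0.0)
  best <- h <= min(h) + 1e-9 * max(1, min(h))
  mean(range(cand[best]))
}

#' Select the ridge penalty by cross-validated policy value
#'
#' For each candidate penalty, refits the OWL rule with each fold held
#' out and records the held-out assignment; the candidate's score is the
#' Hajek inverse-probability value (on the outcome scale, lower = better)
#' aggregated over held-out assignments.  The default is the jackknife
#' (leave-one-out), matching small-sample practice; `method = "kfold"`
#' is provided for larger samples where n refits per candidate are
#' disproportionate.  Ties are broken toward the larger penalty.
#'
#' Folds whose held-out subject has a missing outcome contribute nothing
#' to the score and are skipped; a training fold with no usable weights
#' falls back to the zero rule (with a warning from [fit_owl()]).
#'
#' The hinge term of the OWL objective scales with the subject weights
#' (reward times inverse-probability weight over propensity, of the order
#' of the outcome range), so a penalty grid fixed in absolute units would
#' cover different shrinkage regimes on different datasets.  Candidates
#' are therefore interpreted relative to the mean positive OWL weight:
#' the effective penalty passed to [fit_owl()] is `candidate *
#' mean(w[w > 0])`, making the default grid span near-unregularized
#' through fully collapsed fits on any outcome scale.  Set
#' `scale_by_mean_weight = FALSE` to pass candidates through unchanged.
#'
#' @param dataset A `trial_dataset`.
#' @param r [observation_weights()] for the dataset (held fixed across
#'   folds).
#' @param grid Nonempty vector of candidate penalties (relative units by
#'   default, see above).
#' @param scale_by_mean_weight Interpret `grid` in units of the mean
#'   positive OWL weight (default `TRUE`).
#' @param method `"loocv"` (jackknife) or `"kfold"`.
#' @param k Number of folds for `method = "kfold"`.
#' @param repeats Independent k-fold splits whose CV values are averaged
#'   before selection (k-fold only); repeated CV damps split-randomness
#'   in the selection at proportional cost.
#' @param propensities As in [owl_weights()].
#' @param seed Seed for the fold split (k-fold only; the jackknife is
#'   deterministic).
#' @return Object of class `owl_tuning`: list with `grid` (effective
#'   penalties, the units [fit_owl()] takes), `grid_relative` (as
#'   supplied), `cv_value` (PCL points per candidate), `selected`
#'   (effective units), `assignments` (n x length(grid) matrix of
#'   held-out assignments, `NA` where skipped), `method`.
#' @export
select_lambda <- function(dataset, r, grid = default_lambda_grid(),
                          scale_by_mean_weight = TRUE,
                          method = c("loocv", "kfold"), k = 10,
                          repeats = 1, propensities = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!length(grid)) stop("the penalty grid must be nonempty")
  if (dataset$n < 3) stop("cross-validation needs at least 3 subjects")
  grid_rel <- sort(as.numeric(grid))

  rv <- if (inherits(r, "observation_weights")) r$weights else as.numeric(r)
  B <- compute_rewards(dataset$Y)
  pi_i <- propensity_of_received(dataset$A, propensities)
  w <- owl_weights(B, rv, dataset$A, pi_i)$w
  a <- ifelse(dataset$A == 1, 1, -1)
  n <- dataset$n

  w_scale <- if (scale_by_mean_weight && any(w > 0)) mean(w[w > 0]) else 1
  grid <- grid_rel * w_scale

  n_rep <- if (method == "loocv") 1 else max(1, as.integer(repeats))
  cv_mat <- matrix(NA_real_, n_rep, length(grid))
  assignments <- NULL
  for (rep_i in seq_len(n_rep)) {
    folds <- if (method == "loocv") {
      as.list(which(dataset$observed))   # unobserved subjects never score
    } else {
      idx <- with_seed(derive_seed(seed, 4L + rep_i),
                       sample(rep_len(seq_len(k), n)))
      lapply(seq_len(k), function(f) which(idx == f))
    }
    assign_rep <- matrix(NA_integer_, n, length(grid))
    for (fold in folds) {
      train <- setdiff(seq_len(n), fold)
      for (g in seq_along(grid)) {
        rule <- suppressWarnings(
          fit_owl(dataset$Z[train, , drop = FALSE], dataset$A[train],
                  w[train], grid[g]))
        assign_rep[fold, g] <-
          apply_rule(rule, dataset$Z[fold, , drop = FALSE])$assignment
      }
    }
    cv_mat[rep_i, ] <- vapply(seq_along(grid), function(g) {
      cv_hajek_value(dataset, rv, pi_i, assign_rep[, g])
    }, 0.0)
    if (rep_i == 1) assignments <- assign_rep
  }
  cv_value <- colMeans(cv_mat)

  ok <- is.finite(cv_value)
  if (!any(ok)) stop("no penalty candidate produced a scorable CV value")
  vbest <- min(cv_value[ok])
  selected <- max(grid[ok & cv_value <= vbest + 1e-12])

  structure(list(grid = grid, grid_relative = grid_rel,
                 weight_scale = w_scale, cv_value = cv_value,
                 selected = selected, assignments = assignments,
                 method = method),
            class = "owl_tuning")
}

# Hajek IPW value of a vector of (possibly partially NA) assignments.
cv_hajek_value <- function(dataset, rv, pi_i, d) {
  use <- dataset$observed & !is.na(d) & dataset$A == d
  if (!any(use)) return(NA_real_)
  sum(rv[use] * dataset$Y[use] / pi_i[use]) / sum(rv[use] / pi_i[use])
}

#' Hajek value of an explicit assignment vector
#'
#' The estimator of [estimate_value()] applied to a given vector of
#' assignments rather than to a rule -- used to score cross-validated
#' (held-out) assignments, where each subject's assignment comes from a
#' fit that excluded them.  Entries may be `NA` (subject not scored).
#'
#' @param dataset A `trial_dataset`.
#' @param assignments Integer vector (1 = telehealth, 0 = in-person,
#'   `NA` = skip).
#' @param r [observation_weights()] or weight vector; `NULL` = all
#'   observed weight 1.
#' @param propensities As in [owl_weights()].
#' @return The Hajek value in PCL points.
#' @export
hajek_value <- function(dataset, assignments, r = NULL,
                        propensities = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"),
            length(assignments) == dataset$n)
  rv <- if (is.null(r)) as.numeric(dataset$observed)
  else if (inherits(r, "observation_weights")) r$weights
  else as.numeric(r)
  pi_i <- propensity_of_received(dataset$A, propensities)
  cv_hajek_value(dataset, rv, pi_i, assignments)
}

#' @export
print.owl_tuning <- function(x, ...) {
  cat("Penalty selection by", if (x$method == "loocv")
    "jackknife (leave-one-out)" else "k-fold", "cross-validation\n")
  print(data.frame(lambda = x$grid, cv_value = round(x$cv_value, 3)),
        row.names = FALSE)
  cat("selected lambda:", x$selected, "\n")
  invisible(x)
}

#' Exhaustive weighted-classification oracle for tiny instances
#'
#' Searches linear rules exhaustively for the one maximizing the weighted
#' 0-1 value `sum_i w_i 1{A_i = d(z_i)}`: in one dimension all thresholds
#' in both orientations; in two dimensions all halfplane dichotomies via a
#' dense direction grid augmented with the directions orthogonal to every
#' pairwise difference (which generate all extreme dichotomies), each with
#' all distinct thresholds.  Also reports the unconstrained optimum over
#' all assignments (grouping duplicated rows), a cap no linear rule can
#' exceed.  Refuses instances beyond p = 2 or n = 14; this is a test
#' oracle, not an estimator.
#'
#' @param Z Covariate matrix, at most 2 columns.
#' @param A Arm vector.
#' @param w Nonnegative weights.
#' @param n_angles Direction-grid resolution for p = 2.
#' @return List with `rule` (intercept and slopes of length `ncol(Z)`),
#'   `value` (best linear weighted 0-1 value), and `best_possible` (the
#'   unconstrained cap).
#' @export
brute_force_oracle <- function(Z, A, w, n_angles = 360) {
  Z <- as.matrix(Z)
  n <- nrow(Z); p <- ncol(Z)
  if (p > 2 || n > 14)
    stop("the brute-force oracle is restricted to p <= 2 and n <= 14")
  a <- ifelse(A == 1, 1, -1)
  stopifnot(length(w) == n, all(w >= 0))

  value_of <- function(score) {
    d <- ifelse(score >= 0, 1, -1)
    sum(w[d == a])
  }

  best <- list(value = -Inf, intercept = 0, slopes = rep(0, p))
  consider <- function(b0, beta) {
    v <- value_of(b0 + drop(Z %*% beta))
    if (v > best$value)
      best <<- list(value = v, intercept = b0, slopes = beta)
  }

  consider(1, rep(0, p))    # all telehealth
  consider(-1, rep(0, p))   # all in-person

  directions <- if (p == 1) {
    matrix(c(1, -1), ncol = 1)
  } else {
    ang <- pi * seq(0, n_angles - 1) / n_angles
    dirs <- cbind(cos(ang), sin(ang))
    diffs <- Z[rep(seq_len(n), each = n), , drop = FALSE] -
      Z[rep(seq_len(n), n), , drop = FALSE]
    diffs <- diffs[rowSums(abs(diffs)) > 1e-12, , drop = FALSE]
    if (nrow(diffs)) {
      orth <- cbind(-diffs[, 2], diffs[, 1])
      orth <- orth / sqrt(rowSums(orth^2))
      dirs <- rbind(dirs, orth, -orth)
    }
    dirs
  }

  for (i in seq_len(nrow(directions))) {
    beta <- directions[i, ]
    proj <- drop(Z %*% beta)
    cuts <- sort(unique(proj))
    mids <- if (length(cuts) > 1)
      (cuts[-1] + cuts[-length(cuts)]) / 2 else numeric(0)
    for (t in c(cuts, mids, cuts[1] - 1, cuts[length(cuts)] + 1))
      consider(-t, beta)
  }

  key <- apply(Z, 1, paste, collapse = "\r")
  per_group <- tapply(seq_len(n), key, function(idx) {
    max(sum(w[idx][a[idx] == 1]), sum(w[idx][a[idx] == -1]))
  })
  list(rule = list(intercept = best$intercept, slopes = best$slopes),
       value = best$value, best_possible = sum(per_group))
}

#' Weighted 0-1 value of a rule on a training sample
#'
#' `sum_i w_i 1{A_i = d(z_i)}` -- the classification-side objective that
#' OWL's hinge loss surrogates.
#'
#' @param rule A [decision_rule()] (or list with `intercept`, `slopes`).
#' @param Z Covariate matrix on the rule's scale.
#' @param A Arm vector.
#' @param w Nonnegative weights.
#' @return Scalar value.
#' @export
weighted_value_01 <- function(rule, Z, A, w) {
  score <- drop(rule$intercept + as.matrix(Z) %*%
                  rule$slopes[seq_len(ncol(as.matrix(Z)))])
  d <- as.integer(score >= 0)
  sum(w[d == A])
}

#' Render a rule in indicator notation
#'
#' @param rule A [decision_rule()].
#' @param digits Decimals shown per coefficient.
#' @return A single string, e.g.
#'   `d_opt(X) = I(-0.23 - 0.84 x Age ... >= 0)`.
#' @export
format_rule <- function(rule, digits = 2) {
  labels <- c("Age", "White", "Disability", "Rural", "SES",
              "Baseline PCL-5")
  co <- sprintf(paste0("%.", digits, "f"), abs(rule$slopes))
  sgn <- ifelse(rule$slopes < 0, "-", "+")
  terms <- paste(sgn, co, "x", labels, collapse = " ")
  sprintf("d_opt(X) = I(%.2f %s >= 0)   [1 = telehealth, 0 = in-person]",
          rule$intercept, terms)
}

rule_to_list <- function(rule, provenance = NULL) {
  out <- list(
    coefficients = c(list(intercept = rule$intercept),
                     as.list(rule$slopes)),
    tie = rule$tie,
    standardization = if (!is.null(rule$standardization))
      list(mean = as.list(rule$standardization$mean),
           sd = as.list(rule$standardization$sd)))
  if (!is.null(provenance)) out$provenance <- provenance
  out
}

#' Serialize / restore a decision rule as JSON
#'
#' The JSON bundle carries the named coefficients, the tie convention,
#' the embedded standardization parameters and provenance (seed, penalty,
#' package version), so a saved rule can score future individuals without
#' the training data.
#'
#' @param rule A [decision_rule()].
#' @param path File path.
#' @param provenance Optional named list (seed, lambda, ...).
#' @return `write_rule_json()` returns `path` invisibly;
#'   `read_rule_json()` returns the [decision_rule()] (provenance in the
#'   `"provenance"` attribute).
#' @export
write_rule_json <- function(rule, path, provenance = NULL) {
  prov <- c(list(package = paste0("owlitr ",
                                  as.character(packageVersion("owlitr")))),
            provenance)
  jsonlite::write_json(rule_to_list(rule, prov), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_json
#' @export
read_rule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (!is.null(x$standardization))
    list(mean = unlist(x$standardization$mean),
         sd = unlist(x$standardization$sd))
  rule <- decision_rule(intercept = x$coefficients$intercept,
                        slopes = unlist(x$coefficients[factor_names()]),
                        standardization = std,
                        tie = x$tie %||% "telehealth")
  attr(rule, "provenance") <- x$provenance
  rule
}
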
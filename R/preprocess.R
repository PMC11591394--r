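#' Binarize race and income to the analysis indicators
#'
#' Converts a categorical `race` column to the indicator `white`
#' (1 = White, 0 = Black and all other races) and a categorical `income`
#' bracket column to `low_income` (1 = annual household income below
#' USD 35,000, the lowest-quintile threshold; the five brackets below that
#' bound map to 1, the three at or above it to 0).  Columns already named
#' `white` / `low_income` are passed through untouched.
#'
#' Label matching is insensitive to case, surrounding whitespace and the
#' hyphen/en-dash distinction.  Any unrecognized label is an error naming
#' the offending value.
#'
#' @param raw Data frame with `race` and/or `income` columns (missing
#'   values are allowed and propagate; impute afterwards with
#'   [impute_covariates()]).
#' @return The data frame with `white` and `low_income` numeric columns in
#'   place of `race` / `income`.
#' @export
binarize_demographics <- function(raw) {
  if ("race" %in% names(raw)) {
    raw$white <- binarize_race(raw$race)
    raw$race <- NULL
  }
  if ("income" %in% names(raw)) {
    raw$low_income <- binarize_income(raw$income)
    raw$income <- NULL
  }
  raw
}

squish_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("–|—", "-", x)   # en/em dash -> hyphen
  gsub("[[:space:]]+", "", x)
}

race_levels <- c("White", "Black", "Native American or Alaskan Native",
                 "Asian", "Pacific Islander or Native Hawaiian",
                 "More than one race", "Other")

income_brackets_low <- c("USD 0-<USD 10,000", "USD 10,000-<USD 15,000",
                         "USD 15,000-<USD 20,000", "USD 20,000-<USD 25,000",
                         "USD 25,000-<USD 35,000")
income_brackets_high <- c("USD 35,000-<USD 50,000",
                          "USD 50,000-<USD 75,000", "USD 75,000 or more")

binarize_race <- function(x) {
  key <- squish_label(x)
  valid <- squish_label(race_levels)
  bad <- unique(x[!is.na(x) & !key %in% valid])
  if (length(bad))
    stop("unrecognized race label(s): ", paste(sQuote(bad), collapse = ", "))
  out <- as.numeric(key == squish_label("White"))
  out[is.na(x)] <- NA_real_
  out
}

binarize_income <- function(x) {
  key <- squish_label(x)
  low <- squish_label(income_brackets_low)
  high <- squish_label(income_brackets_high)
  bad <- unique(x[!is.na(x) & !key %in% c(low, high)])
  if (length(bad))
    stop("unrecognized income bracket(s): ",
         paste(sQuote(bad), collapse = ", "))
  out <- as.numeric(key %in% low)
  out[is.na(x)] <- NA_real_
  out
}

#' Single deterministic imputation of missing covariates
#'
#' Binary prescriptive factors are imputed to the mode (ties to 1) and
#' continuous ones to the mean of the observed values.  Counts of imputed
#' entries per column are attached as the `"imputed"` attribute.
#'
#' @param raw Data frame containing the six prescriptive factors
#'   (missingness confined to covariates; the arm must be complete).
#' @return The completed data frame.
#' @export
impute_covariates <- function(raw) {
  binary <- c("white", "disability", "rural", "low_income")
  continuous <- c("age", "pcl_baseline")
  counts <- integer(0)
  for (col in intersect(c(binary, continuous), names(raw))) {
    x <- raw[[col]]
    n_na <- sum(is.na(x))
    if (n_na == length(x))
      stop("column ", sQuote(col), " is entirely missing")
    if (n_na > 0) {
      fill <- if (col %in% binary)
        as.numeric(mean(x, na.rm = TRUE) >= 0.5)
      else
        mean(x, na.rm = TRUE)
      x[is.na(x)] <- fill
      raw[[col]] <- x
      counts[col] <- n_na
    }
  }
  attr(raw, "imputed") <- counts
  raw
}

#' Standardize the prescriptive factors
#'
#' Centers and scales every factor column (binary indicators included) to
#' mean 0 and SD 1, with the sample SD (denominator n - 1).  The returned
#' parameters allow scoring future individuals on the training scale.
#'
#' @param x Data frame or matrix whose columns include the six
#'   prescriptive factors (all complete, each with nonzero variance).
#' @return List with `Z` (standardized matrix, columns in the fixed factor
#'   order) and `params` (list of `mean` and `sd` vectors).
#' @export
standardize_covariates <- function(x) {
  X <- as.matrix(as.data.frame(x)[, factor_names()])
  if (anyNA(X))
    stop("covariates must be complete before standardization")
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev <= 0))
    stop("zero-variance column(s): ",
         paste(names(sdev)[sdev <= 0], collapse = ", "),
         " (the rule would be unidentifiable in that coordinate)")
  params <- list(mean = mu, sd = sdev)
  list(Z = apply_standardization(params, X), params = params)
}

#' @rdname standardize_covariates
#' @param params Standardization parameters (`mean`, `sd`).
#' @param z,raw A covariate row/matrix to transform.
#' @export
apply_standardization <- function(params, raw) {
  X <- if (is.null(dim(raw))) matrix(raw, nrow = 1) else as.matrix(raw)
  if (ncol(X) != length(params$mean))
    stop("covariate row has ", ncol(X), " entries; expected ",
         length(params$mean))
  out <- sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
  colnames(out) <- names(params$mean)
  if (is.null(dim(raw))) drop(out) else out
}

#' @rdname standardize_covariates
#' @export
invert_standardization <- function(params, z) {
  X <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  out <- sweep(sweep(X, 2, params$sd, `*`), 2, params$mean, `+`)
  colnames(out) <- names(params$mean)
  if (is.null(dim(z))) drop(out) else out
}

#' Assemble the analysis-ready intention-to-treat dataset
#'
#' Retains every randomized participant regardless of treatment completion
#' (any completion-status column is ignored), standardizes the six
#' prescriptive factors, and records the outcome missingness mask.
#'
#' @param raw Data frame with the six prescriptive factors (complete;
#'   run [binarize_demographics()] and [impute_covariates()] first), an
#'   `arm` column (1 = telehealth, 0 = in-person, no missing values) and a
#'   `pcl_6month` outcome column (`NA` = missing, observed values in
#'   \[0, 80\]).  An optional `id` column is carried through.
#' @return An object of class `trial_dataset`: list with `ids`, `Z`
#'   (standardized n x 6 matrix), `A`, `Y`, `observed`, `raw` (original
#'   scale covariates), `std_params`, `n`, `n_observed`.
#' @export
assemble_analysis_dataset <- function(raw) {
  need <- c(factor_names(), "arm", "pcl_6month")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(raw$arm)) stop("arm assignment missing for some rows")
  if (!all(raw$arm %in% c(0, 1)))
    stop("arm must be coded 1 = telehealth, 0 = in-person")
  covs <- raw[, factor_names()]
  if (anyNA(covs))
    stop("covariates contain missing values; run impute_covariates() first")
  y <- raw$pcl_6month
  obs <- !is.na(y)
  if (any(y[obs] < 0 | y[obs] > 80))
    stop("observed outcomes must lie in [0, 80]")
  std <- standardize_covariates(covs)
  structure(list(ids = raw$id %||% seq_len(nrow(raw)),
                 Z = std$Z,
                 A = as.integer(raw$arm),
                 Y = as.numeric(y),
                 observed = obs,
                 raw = covs,
                 std_params = std$params,
                 n = nrow(raw),
                 n_observed = sum(obs)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "Trial dataset: n = %d (%d telehealth / %d in-person), %d observed outcomes (%.1f%% missing)\n",
    x$n, sum(x$A == 1), sum(x$A == 0), x$n_observed,
    100 * (1 - x$n_observed / x$n)))
  invisible(x)
}

# Row subset of a trial dataset (used by cross-validation folds and the
# bootstrap).  Standardization parameters are inherited, not recomputed:
# resamples and folds are scored on the training scale.
subset_dataset <- function(dataset, idx) {
  structure(list(ids = dataset$ids[idx],
                 Z = dataset$Z[idx, , drop = FALSE],
                 A = dataset$A[idx],
                 Y = dataset$Y[idx],
                 observed = dataset$observed[idx],
                 raw = dataset$raw[idx, , drop = FALSE],
                 std_params = dataset$std_params,
                 n = length(idx),
                 n_observed = sum(dataset$observed[idx])),
            class = "trial_dataset")
}
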
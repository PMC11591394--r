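#' Full OWL analysis of a trial table
#'
#' Runs the complete pipeline on a raw trial table: binarization (if
#' categorical race/income columns are present), deterministic covariate
#' imputation, standardization, intention-to-treat assembly, observation
#' model and inverse-probability weights, penalty selection by
#' cross-validated value, the final OWL fit on the full data at the
#' selected penalty, and (optionally) the bootstrap performance table.
#'
#' @param trial Data frame in the canonical trial layout (or with raw
#'   `race` / `income` columns).
#' @param lambda_grid Candidate ridge penalties.
#' @param tune `"loocv"` (jackknife; default, suited to small samples),
#'   `"kfold"` (larger samples), or `"none"` (use `lambda` directly).
#' @param lambda Penalty for `tune = "none"` (absolute units, as taken
#'   by [fit_owl()]).
#' @param k Folds for `tune = "kfold"`.
#' @param cv_repeats Averaged k-fold splits (see [select_lambda()]).
#' @param clip_floor Observation-probability floor.
#' @param propensities As in [owl_weights()]; default empirical.
#' @param bootstrap_B Bootstrap replicates for the performance table;
#'   0 skips the table.
#' @param seed Run seed (fans out to tuning and bootstrap stages).
#' @return Object of class `owl_result`: list with `dataset`,
#'   `obs_model`, `obs_weights`, `tuning` (`NULL` when not tuned),
#'   `lambda`, `rule`, `performance` (`NULL` when skipped), `seed`.
#' @export
owl_analysis <- function(trial,
                         lambda_grid = default_lambda_grid(),
                         tune = c("loocv", "kfold", "none"),
                         lambda = NULL, k = 10, cv_repeats = 1,
                         clip_floor = 0.05, propensities = NULL,
                         bootstrap_B = 1000, seed = 1L) {
  tune <- match.arg(tune)
  raw <- impute_covariates(binarize_demographics(as.data.frame(trial)))
  dataset <- assemble_analysis_dataset(raw)

  obs_model <- fit_observation_model(dataset)
  obs_w <- observation_weights(obs_model, dataset, clip_floor = clip_floor)

  tuning <- NULL
  if (tune == "none") {
    if (is.null(lambda)) stop("tune = 'none' requires an explicit lambda")
  } else {
    tuning <- select_lambda(dataset, obs_w, grid = lambda_grid,
                            method = tune, k = k, repeats = cv_repeats,
                            propensities = propensities, seed = seed)
    lambda <- tuning$selected
  }

  B <- compute_rewards(dataset$Y)
  w <- owl_weights(B, obs_w, dataset$A, propensities)
  rule <- fit_owl(dataset$Z, dataset$A, w, lambda,
                  standardization = dataset$std_params)

  cv_assign <- if (!is.null(tuning))
    tuning$assignments[, match(lambda, tuning$grid)]
  performance <- if (bootstrap_B > 0)
    performance_table(dataset, rule, B = bootstrap_B,
                      clip_floor = clip_floor,
                      propensities = propensities,
                      cv_assignments = cv_assign, seed = seed)

  structure(list(dataset = dataset, obs_model = obs_model,
                 obs_weights = obs_w, tuning = tuning, lambda = lambda,
                 rule = rule, cv_assignments = cv_assign,
                 performance = performance, seed = seed),
            class = "owl_result")
}

#' @export
print.owl_result <- function(x, ...) {
  print(x$dataset)
  cat(sprintf("selected penalty lambda = %g (%s)\n", x$lambda,
              if (is.null(x$tuning)) "fixed" else x$tuning$method))
  cat("estimated rule:\n  ", format_rule(x$rule), "\n", sep = "")
  if (!is.null(x$performance)) print(x$performance)
  invisible(x)
}

#' Descriptive characteristics table, by arm
#'
#' Means and SDs with Welch two-sample t-tests for continuous variables;
#' frequencies and percentages with chi-square tests for the binary
#' indicators; percent missing per variable.
#'
#' @param trial Data frame in the canonical trial layout.
#' @return Data frame with one row per variable (continuous) or level
#'   (binary): overall / telehealth / in-person summaries, the
#'   between-arm p-value and percent missing.
#' @export
descriptives_table <- function(trial) {
  trial <- as.data.frame(trial)
  tele <- trial$arm == 1
  rows <- list()
  continuous <- intersect(c("age", "pcl_baseline", "pcl_6month"),
                          names(trial))
  for (v in continuous) {
    x <- trial[[v]]
    p <- tryCatch(t.test(x[tele], x[!tele])$p.value,
                  error = function(e) NA_real_)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      overall = sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                        sd(x, na.rm = TRUE)),
      telehealth = sprintf("%.2f (%.2f)", mean(x[tele], na.rm = TRUE),
                           sd(x[tele], na.rm = TRUE)),
      in_person = sprintf("%.2f (%.2f)", mean(x[!tele], na.rm = TRUE),
                          sd(x[!tele], na.rm = TRUE)),
      p_value = p,
      pct_missing = 100 * mean(is.na(x)))
  }
  binary <- intersect(c("white", "disability", "rural", "low_income"),
                      names(trial))
  for (v in binary) {
    x <- trial[[v]]
    tab <- table(factor(x, levels = 0:1), factor(as.integer(tele),
                                                 levels = 0:1))
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    fmt <- function(sub) sprintf("%d (%.2f%%)", sum(sub == 1, na.rm = TRUE),
                                 100 * mean(sub == 1, na.rm = TRUE))
    rows[[v]] <- data.frame(
      variable = v, type = "binary",
      overall = fmt(x), telehealth = fmt(x[tele]),
      in_person = fmt(x[!tele]), p_value = p,
      pct_missing = 100 * mean(is.na(x)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- file-oriented stage runners (the CLI surface) -----------------------

write_manifest <- function(out_dir, stage, config, seed, files) {
  manifest <- list(stage = stage, seed = seed,
                   package = paste0("owlitr ",
                                    as.character(packageVersion("owlitr"))),
                   config = config,
                   files = as.list(tools::md5sum(files)))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline stage runners
#'
#' File-oriented wrappers tying the stages into reproducible runs; each
#' writes its outputs plus a JSON manifest (configuration, seed and MD5
#' checksums) into `out_dir`.
#'
#' * `run_simulate()`: writes `trial.csv` and `truth.json` for a
#'   synthetic configuration.
#' * `run_fit()`: reads a trial CSV, runs [owl_analysis()] without the
#'   bootstrap, writes `rule.json` and `tuning.csv`.
#' * `run_evaluate()`: reads a trial CSV and a rule JSON, writes the
#'   bootstrap performance table (`performance.csv`), descriptives
#'   (`descriptives.csv`) and a text report restating the rule in
#'   indicator notation (`report.txt`).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Run seed.
#' @param input_csv Path of a trial CSV.
#' @param rule_json Path of a rule JSON written by `run_fit()`.
#' @param ... Passed on to [owl_analysis()] / [performance_table()].
#' @return Named list of written file paths, invisibly.
#' @name pipeline_runners
NULL

#' @rdname pipeline_runners
#' @export
run_simulate <- function(config = synthetic_config(), out_dir,
                         seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- simulate_trial(config, seed = seed)
  trial_path <- file.path(out_dir, "trial.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_trial_csv(trial, trial_path)
  write_truth_json(config, truth_path)
  cfg <- unclass(config)
  cfg[c("control_surface", "interaction_surface", "missingness")] <-
    lapply(cfg[c("control_surface", "interaction_surface", "missingness")],
           as.list)
  manifest <- write_manifest(out_dir, "simulate", cfg, seed,
                             c(trial_path, truth_path))
  invisible(list(trial = trial_path, truth = truth_path,
                 manifest = manifest))
}

#' @rdname pipeline_runners
#' @export
run_fit <- function(input_csv, out_dir, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- read_trial_csv(input_csv)
  res <- owl_analysis(trial, bootstrap_B = 0, seed = seed, ...)
  rule_path <- file.path(out_dir, "rule.json")
  write_rule_json(res$rule, rule_path,
                  provenance = list(seed = seed, lambda = res$lambda,
                                    n = res$dataset$n,
                                    input = basename(input_csv)))
  files <- rule_path
  if (!is.null(res$tuning)) {
    tuning_path <- file.path(out_dir, "tuning.csv")
    write.csv(data.frame(lambda = res$tuning$grid,
                         cv_value = res$tuning$cv_value),
              tuning_path, row.names = FALSE)
    files <- c(files, tuning_path)
  }
  manifest <- write_manifest(
    out_dir, "fit",
    list(input = input_csv, lambda = res$lambda,
         tuning = if (!is.null(res$tuning)) res$tuning$method else "none",
         missing_rate = 1 - res$dataset$n_observed / res$dataset$n),
    seed, files)
  invisible(list(rule = rule_path, manifest = manifest, result = res))
}

#' @rdname pipeline_runners
#' @export
run_evaluate <- function(input_csv, rule_json, out_dir, seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial <- read_trial_csv(input_csv)
  rule <- read_rule_json(rule_json)
  raw <- impute_covariates(binarize_demographics(trial))
  dataset <- assemble_analysis_dataset(raw)
  perf <- performance_table(dataset, rule, seed = seed, ...)
  desc <- descriptives_table(trial)

  perf_path <- file.path(out_dir, "performance.csv")
  desc_path <- file.path(out_dir, "descriptives.csv")
  report_path <- file.path(out_dir, "report.txt")
  write.csv(as.data.frame(perf), perf_path, row.names = FALSE)
  write.csv(desc, desc_path, row.names = FALSE)
  writeLines(c("Individualized treatment rule:", format_rule(rule), "",
               "Performance (PCL points, lower = better):",
               sprintf("  %-24s %s", perf$parameter, perf$formatted)),
             report_path)
  manifest <- write_manifest(out_dir, "evaluate",
                             list(input = input_csv, rule = rule_json),
                             seed, c(perf_path, desc_path, report_path))
  invisible(list(performance = perf_path, descriptives = desc_path,
                 report = report_path, manifest = manifest,
                 table = perf))
}
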
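#' Named simulation scenarios
#'
#' Pre-registered generator configurations used throughout the package's
#' validation studies.
#'
#' * `scenario_default()`: the emulation of the motivating study's
#'   marginals, with moderate treatment-effect heterogeneity and MAR
#'   missingness (the [synthetic_config()] defaults).
#' * `scenario_strong_interaction()`: large, sign-varying interaction
#'   surface (SD about 12 PCL points) with zero average effect, for
#'   rule-recovery and regret studies.  Six-month symptom levels are kept
#'   high (control intercept 55) so the reward `80 - Y` is driven mainly
#'   by the modality effect rather than by its common offset -- the
#'   regime in which the prescriptive signal dominates the weighted
#'   classification (see the methods vignette on the reward anchor).
#' * `scenario_null()`: no treatment-covariate interaction.  `better`
#'   selects a constant effect: `"none"` (exact equivalence),
#'   `"telehealth"`/`"in_person"` (that arm uniformly lowers the outcome
#'   by 8 points).
#' * `scenario_single_covariate(effect)`: interaction loading on age only,
#'   with age marginals chosen so its standardized value is an effectively
#'   untruncated standard normal; the anti-optimal rule then has
#'   closed-form regret `effect * sqrt(2/pi)`.  No missingness.
#'
#' @param n Participants.
#' @param missingness Passed to [synthetic_config()]; `NULL` keeps the
#'   default MAR model.
#' @param better Arm favored in the null scenario.
#' @param effect Age-interaction slope (PCL points per SD of age).
#' @param seed Config seed.
#' @return A [synthetic_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_default <- function(n = 122, seed = 20993L) {
  synthetic_config(n = n, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_strong_interaction <- function(n = 2000, missingness = NULL,
                                        seed = 20993L) {
  synthetic_config(
    n = n,
    control_surface = c(intercept = 55, age = 2, white = 0,
                        disability = 2, rural = 0, low_income = 2,
                        pcl_baseline = 8),
    interaction_surface = c(intercept = 0, age = 8, white = 0,
                            disability = 0, rural = -6, low_income = -4,
                            pcl_baseline = 6),
    noise_sd = 15,
    missingness = missingness,
    seed = seed)
}

#' @rdname scenarios
#' @export
scenario_null <- function(n = 1000,
                          better = c("none", "telehealth", "in_person"),
                          seed = 20993L) {
  better <- match.arg(better)
  shift <- switch(better, none = 0, telehealth = -8, in_person = 8)
  synthetic_config(
    n = n,
    interaction_surface = c(intercept = shift, age = 0, white = 0,
                            disability = 0, rural = 0, low_income = 0,
                            pcl_baseline = 0),
    seed = seed)
}

#' @rdname scenarios
#' @export
scenario_single_covariate <- function(n = 1000, effect = 5,
                                      seed = 20993L) {
  synthetic_config(
    n = n,
    covariates = list(age_mean = 50, age_sd = 8),
    control_surface = c(intercept = 40, age = 0, white = 0,
                        disability = 0, rural = 0, low_income = 0,
                        pcl_baseline = 0),
    interaction_surface = c(intercept = 0, age = effect, white = 0,
                            disability = 0, rural = 0, low_income = 0,
                            pcl_baseline = 0),
    noise_sd = 10,
    missingness = c(intercept = 20, age = 0, white = 0, disability = 0,
                    rural = 0, low_income = 0, pcl_baseline = 0, arm = 0),
    seed = seed)
}
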
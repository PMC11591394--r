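Package: owlitr
Title: Outcome Weighted Learning for Individualized Treatment Rules in
    Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates optimal individualized treatment rules for two-arm
    randomized trials by Outcome Weighted Learning: a weighted support
    vector machine (hinge loss with ridge penalty) whose subject weights
    combine the outcome, inverse-probability-of-observation weights for
    missing outcomes, and treatment propensities.  Includes leave-one-out
    (jackknife) selection of the ridge penalty, Hajek inverse-probability
    estimation of the mean outcome (value) under any rule, bootstrap
    standard errors and Wald confidence intervals contrasting the learned
    rule against one-size-fits-all policies, and a seeded synthetic trial
    generator with known ground truth for validation and regret analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
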
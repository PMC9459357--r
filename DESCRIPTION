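Package: hteforest
Title: Honest Causal Forests for Subgroup and Individual Treatment
    Effects in Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual- and subgroup-level treatment effects in
    two-arm randomized trials with binary outcomes. Implements honest causal
    trees and causal forests with variance-maximizing splits, out-of-bag
    conditional average treatment effect (CATE) prediction with half-sample
    ensemble standard errors, depth-weighted variable importance with
    two-pass importance filtering, augmented inverse propensity weighted
    (AIPW) overall and subgroup average treatment effects, an omnibus
    calibration/heterogeneity test, a logistic recycled-prediction
    (G-computation) baseline with bootstrap uncertainty, post-hoc CATE
    summarization by pruned regression trees and best-tree extraction from a
    regression forest, chained-equation multiple imputation with Rubin's
    rules, and a synthetic trial generator with known potential outcomes for
    validation, emulating the covariate structure of a critical-care
    vasopressor trial in patients aged 65 and over.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    ranger,
    rpart,
    sandwich,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
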
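#' Named simulation designs for validating the estimators
#'
#' Fixed study designs used by the package's validation suite. Each returns a
#' [simulation_config()]; they are deliberately small and analytically
#' transparent so estimator properties (parameter recovery, calibration,
#' CI coverage, type-I error) can be measured against known truth.
#'
#' `design_step_cate()`: a two-level treatment effect, -0.06 for patients
#' with chronic hypertension (prevalence 0.458) and -0.02 otherwise, with a
#' constant control-arm risk. The control-arm risk (default 0.15) is chosen
#' by a power argument: the recovery target is the ordering and size of the
#' two group effects, and at n = 4000 the oracle difference-in-means between
#' the groups has standard error about 0.021 at this risk, so the 0.04
#' effect-size step is identifiable (z about 1.9) with high probability;
#' higher control risks leave even an oracle estimator guessing the ordering.
#' `noise_covariates` optionally appends pure-noise binary covariates.
#'
#' `design_modifier_retention()`: one strong binary effect modifier
#' (tau = -0.25 for carriers, 0 otherwise) plus 8 pure-noise covariates
#' (4 binary, 4 continuous); used to validate that the importance filter
#' retains a genuine modifier among noise.
#'
#' `design_homogeneous()`: constant treatment effect (default -0.03) with a
#' risk model driven by three covariates; the null design for type-I error
#' studies of the heterogeneity test.
#'
#' `design_smooth_cate()`: treatment effect decreasing smoothly in age from
#' -0.02 (age 65) to about -0.10 (age 90), risk mildly increasing in age;
#' used for CI coverage studies.
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param control_risk constant control-arm event probability.
#' @param noise_covariates number of extra binary noise covariates.
#' @param tau constant treatment effect for the homogeneous design.
#' @return A [simulation_config()].
#' @name validation_designs
NULL

#' @rdname validation_designs
#' @export
design_step_cate <- function(n = 4000, seed = 1L, control_risk = 0.15,
                             noise_covariates = 0) {
  covs <- list(list(name = "chronic_hypertension", kind = "binary", p = 0.458))
  if (noise_covariates > 0) {
    for (k in seq_len(noise_covariates)) {
      covs[[length(covs) + 1]] <-
        list(name = paste0("noise_", k), kind = "binary", p = 0.3)
    }
  }
  force(control_risk)
  simulation_config(
    n = n, covariate_spec = covs,
    baseline_risk = function(data) rep(control_risk, nrow(data)),
    cate_fn = cate_step_hypertension(-0.06, -0.02),
    seed = seed)
}

#' @rdname validation_designs
#' @export
design_modifier_retention <- function(n = 2000, seed = 1L) {
  covs <- list(list(name = "modifier", kind = "binary", p = 0.5))
  for (k in 1:4) {
    covs[[length(covs) + 1]] <-
      list(name = paste0("noise_bin_", k), kind = "binary", p = 0.3)
  }
  for (k in 1:4) {
    covs[[length(covs) + 1]] <-
      list(name = paste0("noise_cont_", k), kind = "continuous",
           dist = "normal", mean = 0, sd = 1)
  }
  simulation_config(
    n = n, covariate_spec = covs,
    baseline_risk = function(data) rep(0.45, nrow(data)),
    cate_fn = function(data) ifelse(data$modifier == 1, -0.25, 0),
    seed = seed)
}

#' @rdname validation_designs
#' @export
design_homogeneous <- function(n = 1000, seed = 1L, tau = -0.03) {
  covs <- list(
    list(name = "chronic_hypertension", kind = "binary", p = 0.458),
    list(name = "severity", kind = "continuous", dist = "normal",
         mean = 0, sd = 1),
    list(name = "age", kind = "continuous", dist = "truncnorm",
         mean = 75.2, sd = 6.8, lower = 65))
  simulation_config(
    n = n, covariate_spec = covs,
    baseline_risk = function(data) {
      plogis(qlogis(0.3) + 0.4 * data$severity + 0.2 * (data$age - 75.2) / 6.8)
    },
    cate_fn = cate_constant(tau),
    seed = seed)
}

#' @rdname validation_designs
#' @export
design_smooth_cate <- function(n = 4000, seed = 1L) {
  covs <- list(
    list(name = "age", kind = "continuous", dist = "truncnorm",
         mean = 75.2, sd = 6.8, lower = 65),
    list(name = "chronic_hypertension", kind = "binary", p = 0.458))
  simulation_config(
    n = n, covariate_spec = covs,
    baseline_risk = function(data) {
      plogis(qlogis(0.3) + 0.25 * (data$age - 75.2) / 6.8)
    },
    cate_fn = function(data) -0.02 - 0.08 * pmin(1, (data$age - 65) / 25),
    seed = seed)
}
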
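#' Doubly robust (AIPW) scores for every patient
#'
#' Computes the augmented inverse propensity weighted score
#' \deqn{\Gamma_i = \hat\tau_i + D_i (Y_i - \hat m(x_i, 1))/e -
#'       (1 - D_i)(Y_i - \hat m(x_i, 0))/(1 - e)}
#' where \eqn{\hat\tau_i} is the out-of-bag forest CATE and
#' \eqn{\hat m(x, d)} are arm-specific outcome predictions. By default the
#' outcome predictions are the forest's own honest per-leaf arm means,
#' aggregated out-of-bag, so the outcome model is fit honestly on the same
#' subsamples as the effects. Group means of \eqn{\Gamma_i} estimate (group)
#' average treatment effects.
#'
#' @param model a fitted `causal_forest`, or `NULL` when `mu_hat` supplies an
#'   external (e.g. oracle) outcome model.
#' @param trial the training `trial_table` (used for outcomes and ids).
#' @param e randomization probability in (0, 1); defaults to the design
#'   propensity recorded on the model. Set `estimate = TRUE` to use the
#'   empirical treated fraction instead (observational use).
#' @param mu_hat optional list with numeric vectors `mu0`, `mu1` (and
#'   optionally `tau`) overriding the forest outcome model, e.g. an oracle
#'   in simulations.
#' @param estimate logical; estimate the propensity as the sample treated
#'   fraction instead of using the design value.
#' @return A data frame of class `aipw_scores` with columns `id`, `gamma`,
#'   `tau_oob`, `mu0`, `mu1`, `treatment`; the propensity is recorded as an
#'   attribute.
#' @export
aipw_scores <- function(model, trial, e = NULL, mu_hat = NULL,
                        estimate = FALSE) {
  if (is.null(mu_hat)) {
    stopifnot(inherits(model, "causal_forest"))
  } else if (!is.null(model)) {
    stopifnot(inherits(model, "causal_forest"))
  }
  D <- as.numeric(trial$treatment)
  Y <- as.numeric(trial$outcome)
  e <- e %||% (if (estimate) mean(D) else
    (if (!is.null(model)) model$propensity else
      attr(trial, "propensity") %||% 0.5))
  if (!is_scalar_number(e) || e <= 0 || e >= 1) {
    stopf("propensity e must lie strictly in (0, 1)")
  }
  if (is.null(mu_hat)) {
    comp <- predict_components(model, newdata = NULL)
    mu0 <- comp$mu0
    mu1 <- comp$mu1
    tau <- comp$tau
  } else {
    mu0 <- mu_hat$mu0
    mu1 <- mu_hat$mu1
    tau <- mu_hat$tau %||% (mu1 - mu0)
    stopifnot(length(mu0) == nrow(trial), length(mu1) == nrow(trial))
  }
  gamma <- tau + D * (Y - mu1) / e - (1 - D) * (Y - mu0) / (1 - e)
  out <- data.frame(id = trial$id %||% seq_len(nrow(trial)),
                    gamma = gamma, tau_oob = tau, mu0 = mu0, mu1 = mu1,
                    treatment = D)
  class(out) <- c("aipw_scores", "data.frame")
  attr(out, "propensity") <- e
  out
}

#' Subgroup average treatment effect from AIPW scores
#'
#' The group ATE estimate is the mean doubly robust score over the subgroup;
#' its standard error is the score standard deviation divided by the square
#' root of the group size. Group estimates are exactly decomposable: over any
#' partition, the size-weighted mean of group estimates equals the overall
#' estimate.
#'
#' @param scores an `aipw_scores` data frame.
#' @param group logical vector selecting a nonempty subgroup (default: all
#'   rows, giving the overall ATE).
#' @param label subgroup label for reporting.
#' @param level confidence level.
#' @return A one-row data frame of class `group_ate_result` with columns
#'   `label`, `n`, `estimate`, `se`, `ci_low`, `ci_high`, `method`,
#'   `se_reliable`.
#' @export
group_ate <- function(scores, group = NULL, label = "overall", level = 0.95) {
  stopifnot(inherits(scores, "aipw_scores"))
  group <- group %||% rep(TRUE, nrow(scores))
  stopifnot(is.logical(group), length(group) == nrow(scores))
  n_g <- sum(group)
  if (n_g < 1) stopf("group is empty")
  g <- scores$gamma[group]
  est <- mean(g)
  se_ok <- n_g >= 2
  se <- if (se_ok) sd(g) / sqrt(n_g) else NA_real_
  if (!se_ok) warnf("subgroup '%s' has fewer than 2 rows; SE unreliable", label)
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(label = label, n = n_g, estimate = est, se = se,
                    ci_low = est - z * se, ci_high = est + z * se,
                    method = "causal_forest_aipw", se_reliable = se_ok)
  class(out) <- c("group_ate_result", "data.frame")
  out
}

#' Group ATEs for every level of a set of subgroup variables
#'
#' Builds the forest-plot substrate: one row per (subgroup variable, level),
#' with AIPW estimates. Continuous variables should be discretized first
#' (e.g. with [quintile_groups()]).
#'
#' @param scores an `aipw_scores` data frame.
#' @param subgroups data frame of subgroup variables (factor or binary), one
#'   row per patient in `scores` order.
#' @param level confidence level.
#' @return A data frame of class `group_ate_result` with one row per
#'   subgroup level plus an `overall` row, and columns `subgroup_variable`
#'   and `level` identifying the rows.
#' @export
group_ate_table <- function(scores, subgroups, level = 0.95) {
  stopifnot(nrow(subgroups) == nrow(scores))
  rows <- list()
  overall <- group_ate(scores, label = "overall", level = level)
  overall$subgroup_variable <- "overall"
  overall$level_label <- "all"
  rows[[1]] <- overall
  for (v in names(subgroups)) {
    x <- subgroups[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(x))
    for (l in lv) {
      sel <- !is.na(x) & x == l
      if (!any(sel)) next
      r <- group_ate(scores, sel, label = sprintf("%s=%s", v, l),
                     level = level)
      r$subgroup_variable <- v
      r$level_label <- as.character(l)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_ate_result", "data.frame")
  out
}
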
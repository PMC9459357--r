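#' Fit the subgroup logistic model
#'
#' Maximum-likelihood fit of the outcome on an intercept, a binary subgroup
#' indicator G, the treatment indicator D, and their interaction:
#' `logit P(Y=1) = b0 + beta_G G + alpha1 D + alpha2 D G` (the saturated 2x2
#' cell-probability model). An identity-link variant (linear probability
#' model) is available, under which the interaction contrast equals `alpha2`
#' exactly.
#'
#' @param trial a `trial_table`.
#' @param group logical (or 0/1) subgroup indicator, one per row.
#' @param link `"logit"` (default) or `"identity"`.
#' @return An object of class `subgroup_logistic_model` with elements
#'   `coefficients` (named `intercept`, `beta_G`, `alpha1`, `alpha2`),
#'   `link`, `fit`, `converged`.
#' @export
fit_subgroup_model <- function(trial, group, link = c("logit", "identity")) {
  link <- match.arg(link)
  G <- as.numeric(group)
  D <- as.numeric(trial$treatment)
  Y <- as.numeric(trial$outcome)
  stopifnot(length(G) == length(Y), all(G %in% c(0, 1)))
  if (length(unique(D)) < 2) stopf("both treatment arms must be present")
  if (length(unique(G)) < 2) stopf("both subgroup levels must be present")
  if (sum(Y) == 0 || sum(Y) == length(Y)) {
    stopf("outcome needs at least one event and one non-event")
  }
  if (link == "logit") {
    # saturated-model separation check: a (G, D) cell with all events or all
    # non-events sends the corresponding logit to +/- infinity
    for (g in 0:1) for (d in 0:1) {
      yc <- Y[G == g & D == d]
      if (length(yc) > 0 && (mean(yc) == 0 || mean(yc) == 1)) {
        stopf(paste0("complete separation: cell G=%d, D=%d has %s events; ",
                     "logistic fit is not identified"), g, d,
              if (mean(yc) == 0) "no" else "only")
      }
    }
    fit <- glm(Y ~ G * D, family = binomial())
    converged <- fit$converged
  } else {
    fit <- lm(Y ~ G * D)
    converged <- TRUE
  }
  b <- coef(fit)
  if (anyNA(b)) stopf("subgroup model is rank deficient (empty cell?)")
  if (!converged) stopf("subgroup model failed to converge")
  structure(list(coefficients = c(intercept = unname(b["(Intercept)"]),
                                  beta_G = unname(b["G"]),
                                  alpha1 = unname(b["D"]),
                                  alpha2 = unname(b["G:D"])),
                 link = link, fit = fit, converged = converged),
            class = "subgroup_logistic_model")
}

#' Recycled-prediction (G-computation) contrasts
#'
#' Predicts every patient's outcome under each combination of treatment `d`
#' and subgroup membership `g`, then averages: the total effect for the
#' subgroup is `mean(Yhat(1,1) - Yhat(0,1))` and the interaction effect is
#' `mean(Yhat(1,1) - (Yhat(0,1) + Yhat(1,0) - Yhat(0,0)))`, both on the risk
#' (probability) scale.
#'
#' @param model a fitted `subgroup_logistic_model`.
#' @param trial the `trial_table` to recycle predictions over.
#' @return An object of class `gcomputation_contrasts` with the per-patient
#'   prediction matrix (columns `y_d0_g0`, `y_d1_g0`, `y_d0_g1`, `y_d1_g1`),
#'   `total_effect`, `total_effect_complement` (the d-contrast at g = 0) and
#'   `interaction_effect`.
#' @export
gcomp_effects <- function(model, trial) {
  stopifnot(inherits(model, "subgroup_logistic_model"))
  n <- nrow(trial)
  b <- model$coefficients
  linkinv <- if (model$link == "logit") plogis else identity
  pred <- function(d, g) {
    rep(linkinv(b[["intercept"]] + b[["beta_G"]] * g + b[["alpha1"]] * d +
                  b[["alpha2"]] * d * g), n)
  }
  P <- cbind(y_d0_g0 = pred(0, 0), y_d1_g0 = pred(1, 0),
             y_d0_g1 = pred(0, 1), y_d1_g1 = pred(1, 1))
  structure(list(
    predictions = P,
    total_effect = mean(P[, "y_d1_g1"] - P[, "y_d0_g1"]),
    total_effect_complement = mean(P[, "y_d1_g0"] - P[, "y_d0_g0"]),
    interaction_effect = mean(P[, "y_d1_g1"] -
                                (P[, "y_d0_g1"] + P[, "y_d1_g0"] - P[, "y_d0_g0"]))),
    class = "gcomputation_contrasts")
}

#' Nonparametric bootstrap of an effect statistic
#'
#' Case-resampling bootstrap of a full fit-and-contrast procedure: `stat_fn`
#' receives a resampled trial table and returns a numeric scalar (or named
#' vector). Replicates that error (e.g. non-convergence on a degenerate
#' resample) are dropped; more than 20% failures aborts.
#'
#' @param stat_fn function of a `trial_table` returning the statistic.
#' @param trial the `trial_table` to resample.
#' @param B_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed; the same seed reproduces the same CI.
#' @param level confidence level for the percentile interval.
#' @return A list with `estimate` (on the original data), `se`, `ci_low`,
#'   `ci_high` (percentile), `B_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(stat_fn, trial, B_boot = 1000, seed = 1L,
                         level = 0.95) {
  stopifnot(B_boot >= 100)
  est <- stat_fn(trial)
  k <- length(est)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, B_boot, k)
    for (b in seq_len(B_boot)) {
      idx <- sample.int(nrow(trial), replace = TRUE)
      res <- tryCatch(stat_fn(trial[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(res) && length(res) == k) out[b, ] <- as.numeric(res)
    }
    out
  })
  failed <- sum(!complete.cases(reps))
  if (failed > 0.2 * B_boot) {
    stopf("%d of %d bootstrap replicates failed; data too sparse", failed,
          B_boot)
  }
  reps <- reps[complete.cases(reps), , drop = FALSE]
  alpha <- (1 - level) / 2
  out <- list(estimate = est,
              se = apply(reps, 2, sd),
              ci_low = apply(reps, 2, quantile, probs = alpha, names = FALSE),
              ci_high = apply(reps, 2, quantile, probs = 1 - alpha,
                              names = FALSE),
              B_boot = B_boot, n_failed = failed)
  if (!is.null(names(est))) {
    out$se <- setNames(out$se, names(est))
    out$ci_low <- setNames(out$ci_low, names(est))
    out$ci_high <- setNames(out$ci_high, names(est))
  }
  out
}

# overall ATE by recycled predictions from a treatment-only logistic model
logistic_overall_ate <- function(trial) {
  Y <- as.numeric(trial$outcome)
  D <- as.numeric(trial$treatment)
  fit <- glm(Y ~ D, family = binomial())
  b <- coef(fit)
  plogis(b[[1]] + b[[2]]) - plogis(b[[1]])
}

#' Logistic recycled-prediction group ATE table
#'
#' The fixed-parametric comparator: for each subgroup variable and level, a
#' one-vs-rest subgroup logistic model is fit and the total effect for the
#' subgroup obtained by recycled predictions, with bootstrap standard errors
#' and percentile CIs. An `overall` row uses a treatment-only logistic model.
#'
#' @param trial a `trial_table`.
#' @param subgroups data frame of subgroup variables (factor or binary).
#' @param B_boot bootstrap replicates per row.
#' @param seed integer seed.
#' @param level confidence level.
#' @return A `group_ate_result` data frame with `method = "logistic_gcomp"`.
#' @export
logistic_gate_table <- function(trial, subgroups, B_boot = 1000, seed = 1L,
                                level = 0.95) {
  stopifnot(nrow(subgroups) == nrow(trial))
  rows <- list()
  ov <- bootstrap_ci(logistic_overall_ate, trial, B_boot,
                     seed = stage_seed(seed, "boot-overall"), level = level)
  rows[[1]] <- data.frame(label = "overall", n = nrow(trial),
                          estimate = unname(ov$estimate), se = unname(ov$se),
                          ci_low = unname(ov$ci_low),
                          ci_high = unname(ov$ci_high),
                          method = "logistic_gcomp", se_reliable = TRUE,
                          subgroup_variable = "overall", level_label = "all")
  for (v in names(subgroups)) {
    x <- subgroups[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(x))
    for (l in lv) {
      sel <- !is.na(x) & x == l
      if (!any(sel) || all(sel)) next
      stat <- local({
        xl <- x; ll <- l
        function(tr) {
          g <- !is.na(xl[tr$.boot_idx %||% seq_len(nrow(tr))]) &
            xl[tr$.boot_idx %||% seq_len(nrow(tr))] == ll
          gcomp_effects(fit_subgroup_model(tr, g), tr)$total_effect
        }
      })
      # carry the resample indices so the subgroup indicator follows the rows
      trial2 <- trial
      trial2$.boot_idx <- seq_len(nrow(trial))
      bt <- tryCatch(
        bootstrap_ci(stat, trial2, B_boot,
                     seed = stage_seed(seed, paste0("boot-", v, "-", l)),
                     level = level),
        error = function(e) NULL)
      if (is.null(bt)) next
      rows[[length(rows) + 1]] <- data.frame(
        label = sprintf("%s=%s", v, l), n = sum(sel),
        estimate = unname(bt$estimate), se = unname(bt$se),
        ci_low = unname(bt$ci_low), ci_high = unname(bt$ci_high),
        method = "logistic_gcomp", se_reliable = TRUE,
        subgroup_variable = v, level_label = as.character(l))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_ate_result", "data.frame")
  out
}
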
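#' Chained-equation multiple imputation of baseline covariates
#'
#' Iterative chained regressions over the covariates with missing cells,
#' initialized from random draws of each variable's observed values:
#' continuous variables are imputed by predictive mean matching (linear
#' regression on all other covariates plus treatment and outcome, matching
#' each missing case to one of the `donors` observed values with the closest
#' fitted mean, so imputed values are always observed values); binary
#' variables by logistic regression draws; categorical variables by
#' multinomial regression draws. Treatment, outcome and synthetic truth
#' columns are never imputed and never altered.
#'
#' @param trial a `trial_table`, possibly with missing covariate cells.
#' @param m number of completed datasets (>= 1).
#' @param iterations chained-equation sweeps per dataset (default 5).
#' @param seed integer seed.
#' @param donors donor pool size for predictive mean matching.
#' @return An object of class `imputation_set`: list with `completed`
#'   (list of `m` trial tables), `methods` (per-variable imputation method),
#'   `m`, `iterations`, `seed`.
#' @export
mice_impute <- function(trial, m = 5, iterations = 5, seed = 1L,
                        donors = 5) {
  stopifnot(m >= 1, iterations >= 1)
  covs <- baseline_covariates(trial)
  fully_missing <- covs[vapply(covs, function(v) all(is.na(trial[[v]])), TRUE)]
  if (length(fully_missing) > 0) {
    stopf("covariate(s) 100%% missing, cannot impute: %s",
          paste(fully_missing, collapse = ", "))
  }
  miss_vars <- covs[vapply(covs, function(v) anyNA(trial[[v]]), TRUE)]
  methods <- vapply(covs, function(v) {
    x <- trial[[v]]
    if (is.factor(x) || is.character(x)) {
      if (length(unique(x[!is.na(x)])) > 2) "multinomial" else "logistic"
    } else if (all(x[!is.na(x)] %in% c(0, 1))) "logistic" else "pmm"
  }, "")
  names(methods) <- covs

  if (length(miss_vars) == 0) {
    return(structure(list(completed = replicate(m, trial, simplify = FALSE),
                          methods = methods, m = m, iterations = iterations,
                          seed = seed), class = "imputation_set"))
  }

  completed <- vector("list", m)
  for (k in seq_len(m)) {
    completed[[k]] <- with_seed(stage_seed(seed, paste0("imputation-", k)), {
      impute_once(trial, covs, miss_vars, methods, iterations, donors)
    })
  }
  structure(list(completed = completed, methods = methods, m = m,
                 iterations = iterations, seed = seed),
            class = "imputation_set")
}

impute_once <- function(trial, covs, miss_vars, methods, iterations, donors) {
  filled <- trial
  na_idx <- lapply(miss_vars, function(v) which(is.na(trial[[v]])))
  names(na_idx) <- miss_vars
  # order variables by increasing missingness, as chained-equation
  # implementations conventionally do
  miss_vars <- miss_vars[order(vapply(na_idx[miss_vars], length, 0L))]
  for (v in miss_vars) {
    obs <- filled[[v]][!is.na(filled[[v]])]
    filled[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]),
                                       replace = TRUE)
  }
  for (it in seq_len(iterations)) {
    for (v in miss_vars) {
      idx <- na_idx[[v]]
      others <- setdiff(covs, v)
      rhs <- filled[, others, drop = FALSE]
      rhs$.treatment <- filled$treatment
      rhs$.outcome <- filled$outcome
      # drop constant columns, which break the regressions
      keep <- vapply(rhs, function(x) length(unique(x)) > 1, TRUE)
      rhs <- rhs[, keep, drop = FALSE]
      target <- filled[[v]]
      target[idx] <- NA
      fit_df <- cbind(data.frame(.y = target), rhs)
      imputed <- tryCatch(
        impute_variable(fit_df, idx, methods[[v]], donors),
        error = function(e) NULL)
      if (is.null(imputed)) {
        # degenerate regression (e.g. separation on a tiny subsample):
        # fall back to observed-value draws for this sweep
        obs <- filled[[v]][-idx]
        imputed <- sample(obs, length(idx), replace = TRUE)
      }
      filled[[v]][idx] <- imputed
    }
  }
  filled
}

impute_variable <- function(fit_df, idx, method, donors) {
  train <- fit_df[-idx, , drop = FALSE]
  test <- fit_df[idx, , drop = FALSE]
  if (method == "pmm") {
    fit <- lm(.y ~ ., data = train)
    pred_obs <- predict(fit, newdata = train)
    pred_mis <- predict(fit, newdata = test)
    y_obs <- train$.y
    vapply(pred_mis, function(p) {
      pool <- order(abs(pred_obs - p))[seq_len(min(donors, length(pred_obs)))]
      y_obs[pool[sample.int(length(pool), 1)]]
    }, y_obs[1])
  } else if (method == "logistic") {
    y <- train$.y
    lv <- NULL
    if (is.factor(y) || is.character(y)) {
      lv <- if (is.factor(y)) levels(droplevels(factor(y))) else sort(unique(y))
      train$.y <- as.numeric(factor(y, levels = lv)) - 1
    }
    fit <- suppressWarnings(glm(.y ~ ., data = train, family = binomial()))
    p <- predict(fit, newdata = test, type = "response")
    draw <- rbinom(length(p), 1L, p)
    if (is.null(lv)) draw else factor(lv[draw + 1], levels = levels(fit_df$.y))
  } else {
    fit <- suppressWarnings(
      nnet::multinom(.y ~ ., data = train, trace = FALSE))
    p <- predict(fit, newdata = test, type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(test))
    lv <- colnames(p) %||% levels(droplevels(factor(train$.y)))
    picks <- apply(p, 1, function(pr) sample(seq_along(pr), 1, prob = pr))
    factor(lv[picks], levels = levels(fit_df$.y))
  }
}

#' Combine estimates across imputations with Rubin's rules
#'
#' Pooled estimate `Qbar = mean(estimates)`; within-imputation variance
#' `W = mean(variances)`; between-imputation variance `B = var(estimates)`;
#' total variance `T = W + (1 + 1/m) B`; degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`).
#'
#' @param estimates numeric vector of `m >= 2` point estimates.
#' @param variances numeric vector of their `m` squared standard errors.
#' @param level confidence level.
#' @return A list of class `rubin_combined` with `estimate`, `within`,
#'   `between`, `total`, `se`, `df`, `ci_low`, `ci_high`, `m`.
#' @export
rubin_combine <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 2) stopf("Rubin's rules need m >= 2 estimates")
  stopifnot(length(variances) == m, all(variances >= 0))
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- var(estimates)
  total <- w + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + w / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(total)
  tq <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
    qnorm(1 - (1 - level) / 2)
  structure(list(estimate = qbar, within = w, between = b, total = total,
                 se = se, df = df, ci_low = qbar - tq * se,
                 ci_high = qbar + tq * se, m = m),
            class = "rubin_combined")
}

#' Write an imputation set as CSV files plus a JSON manifest
#'
#' @param imp an `imputation_set`.
#' @param dir output directory (created if needed); files are
#'   `imputation_1.csv` ... `imputation_m.csv` and `imputations.json`.
#' @return Invisibly, the manifest path.
#' @export
write_imputation_set <- function(imp, dir) {
  stopifnot(inherits(imp, "imputation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(imp$m)
  for (k in seq_len(imp$m)) {
    paths[k] <- file.path(dir, sprintf("imputation_%d.csv", k))
    write_trial(imp$completed[[k]], paths[k])
  }
  manifest <- file.path(dir, "imputations.json")
  jsonlite::write_json(list(m = imp$m, iterations = imp$iterations,
                            seed = imp$seed, methods = as.list(imp$methods),
                            files = basename(paths)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
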
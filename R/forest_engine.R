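#' Causal forest configuration
#'
#' @param num_trees number of causal trees in the ensemble (default 5000).
#'   Rounded up to an even number so trees come in pairs sharing a
#'   half-sample (used by the variance estimator).
#' @param subsample_fraction fraction of the sample each tree is grown on
#'   (drawn without replacement from the tree pair's half-sample, so the
#'   effective fraction is capped at 0.5).
#' @param honesty_fraction fraction of each subsample used to choose splits;
#'   the remainder estimates leaf effects (honesty).
#' @param min_leaf_per_arm minimum number of treated and control observations
#'   every leaf must retain, on both the split and estimate halves.
#' @param mtry number of candidate variables per split: a positive integer,
#'   `"sqrt"` for `ceiling(sqrt(p))`, or `NULL` (default) for
#'   `min(p, ceiling(sqrt(p)) + 20)`.
#' @param max_depth maximum tree depth, `Inf` for unlimited.
#' @param importance_multiplier variables with importance at or above
#'   `importance_multiplier` times the mean importance are retained for the
#'   second fitting pass; 0 disables filtering (single pass).
#' @param importance_decay exponent of the depth weights `d^(-decay)` in the
#'   split-frequency importance (depths 1..4 considered).
#' @param ci_group_size trees per half-sample group (2 enables the paired
#'   half-sample variance estimator; 1 disables standard errors).
#' @param seed integer seed; fits are deterministic given the seed.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(num_trees = 5000, subsample_fraction = 0.5,
                          honesty_fraction = 0.5, min_leaf_per_arm = 5,
                          mtry = NULL, max_depth = Inf,
                          importance_multiplier = 1, importance_decay = 2,
                          ci_group_size = 2, seed = 1L) {
  stopifnot(is_scalar_number(num_trees), num_trees >= 1,
            is_scalar_number(subsample_fraction), subsample_fraction > 0,
            subsample_fraction <= 1,
            is_scalar_number(honesty_fraction), honesty_fraction > 0,
            honesty_fraction < 1,
            is_scalar_number(min_leaf_per_arm), min_leaf_per_arm >= 1,
            is_scalar_number(importance_multiplier),
            importance_multiplier >= 0,
            is_scalar_number(importance_decay),
            ci_group_size %in% c(1, 2),
            is_scalar_number(seed))
  if (!is.null(mtry) && !identical(mtry, "sqrt")) {
    stopifnot(is_scalar_number(mtry), mtry >= 1)
  }
  structure(list(num_trees = as.integer(num_trees),
                 subsample_fraction = subsample_fraction,
                 honesty_fraction = honesty_fraction,
                 min_leaf_per_arm = as.integer(min_leaf_per_arm),
                 mtry = mtry,
                 max_depth = if (is.finite(max_depth)) as.integer(max_depth) else -1L,
                 importance_multiplier = importance_multiplier,
                 importance_decay = importance_decay,
                 ci_group_size = as.integer(ci_group_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(mtry, p) {
  if (is.null(mtry)) return(min(p, as.integer(ceiling(sqrt(p))) + 20L))
  if (identical(mtry, "sqrt")) return(max(1L, as.integer(ceiling(sqrt(p)))))
  min(p, as.integer(mtry))
}

#' Encode trial covariates as a numeric matrix
#'
#' Factors and characters are one-hot encoded (one column per level, named
#' `variable=level`); logicals and numerics pass through. An `encoding`
#' attribute records the factor levels so new data are encoded consistently;
#' levels unseen at fit time produce all-zero indicator columns and are
#' thereby routed like the reference pattern.
#'
#' @param data a `trial_table` or data frame.
#' @param covariates covariate column names (default: baseline covariates).
#' @param encoding a previously returned encoding to reuse.
#' @return Numeric matrix with an `encoding` attribute.
#' @export
encode_covariates <- function(data, covariates = NULL, encoding = NULL) {
  covariates <- covariates %||% baseline_covariates(data)
  if (!is.null(encoding)) covariates <- names(encoding)
  cols <- list()
  enc <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) stopf("covariate '%s' not found", cv)
    if (anyNA(x)) {
      stopf("covariate '%s' contains missing values; impute first", cv)
    }
    lv <- if (!is.null(encoding)) encoding[[cv]] else
      if (is.factor(x)) levels(x) else if (is.character(x)) sort(unique(x)) else NULL
    if (length(lv) == 1 && is.na(lv[1])) lv <- NULL  # numeric sentinel
    if (is.null(lv)) {
      cols[[cv]] <- as.numeric(x)
      enc[[cv]] <- NA
    } else {
      x <- as.character(x)
      if (!is.null(encoding) && !all(x %in% lv)) {
        warnf("covariate '%s' has levels unseen at fit time (%s); routed by the all-zero indicator pattern",
              cv, paste(setdiff(unique(x), lv), collapse = ", "))
      }
      for (l in lv) cols[[paste0(cv, "=", l)]] <- as.numeric(x == l)
      enc[[cv]] <- lv
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  attr(X, "encoding") <- enc
  X
}

check_trial_arms <- function(treatment) {
  if (!all(treatment %in% c(0, 1))) stopf("treatment must be binary 0/1")
  if (length(unique(treatment)) < 2) {
    stopf("both treatment arms must be present")
  }
}

#' Fit a single honest causal tree
#'
#' Splits are chosen on the split half of the subsample to maximize the
#' between-child heterogeneity of the difference-in-means treatment effect
#' (sum over children of `n_child * tau_child^2`), subject to a per-arm
#' minimum leaf size on both halves; leaf effects are the treated-minus-
#' control mean outcome on the disjoint estimate half. If no candidate split
#' is valid the tree is a single leaf.
#'
#' @param trial a `trial_table` with complete covariates.
#' @param config a [forest_config()].
#' @param subsample integer row indices to grow the tree on (default: all
#'   rows); must contain both arms.
#' @param split_ids,est_ids optional explicit disjoint honesty halves
#'   (row indices); when omitted the subsample is split at random using the
#'   config seed.
#' @return An object of class `causal_tree` with the node arrays, the two
#'   honesty samples, and the covariate encoding.
#' @export
fit_causal_tree <- function(trial, config = forest_config(),
                            subsample = NULL, split_ids = NULL,
                            est_ids = NULL) {
  X <- encode_covariates(trial)
  Y <- as.numeric(trial$outcome)
  D <- as.integer(trial$treatment)
  subsample <- subsample %||% seq_len(nrow(X))
  if (length(unique(D[subsample])) < 2) {
    stopf("subsample must contain both treatment arms")
  }
  if (is.null(split_ids) || is.null(est_ids)) {
    split_ids <- with_seed(config$seed, {
      perm <- sample(subsample)
      perm[seq_len(max(1, floor(config$honesty_fraction * length(perm))))]
    })
    est_ids <- setdiff(subsample, split_ids)
  }
  if (length(intersect(split_ids, est_ids)) > 0) {
    stopf("split and estimate samples must be disjoint (honesty)")
  }
  p <- ncol(X)
  tree <- .cf_fit_tree(X, Y, D, as.integer(split_ids), as.integer(est_ids),
                       config$min_leaf_per_arm, resolve_mtry(config$mtry, p),
                       config$max_depth, as.double(config$seed))
  structure(list(tree = tree, split_ids = sort(split_ids),
                 est_ids = sort(est_ids),
                 covariate_names = colnames(X),
                 encoding = attr(X, "encoding"), config = config),
            class = "causal_tree")
}

#' Predict leaf effects of a single causal tree
#' @param object a `causal_tree`.
#' @param newdata data frame of covariates (default: not supported; supply
#'   the rows to predict).
#' @param ... unused.
#' @return Numeric vector of honest leaf effects for each row.
#' @export
predict.causal_tree <- function(object, newdata, ...) {
  X <- encode_covariates(newdata, encoding = object$encoding)
  X <- X[, object$covariate_names, drop = FALSE]
  .cf_predict_raw(list(object$tree), X)$tau[, 1]
}

#' Fit an honest causal forest with importance-based variable filtering
#'
#' Two-pass procedure: a first forest is grown on all encoded covariates and
#' its depth-weighted split-frequency importances computed; covariates with
#' importance at or above `importance_multiplier` times the mean importance
#' are retained and the forest refit on them. If every covariate is retained
#' (e.g. multiplier 0) the first-pass forest is returned unchanged and the
#' model is flagged single-pass. If filtering would discard everything, the
#' single most important covariate is kept with a warning.
#'
#' Trees are grown in pairs sharing a random half-sample of the data, which
#' supports the paired half-sample (bootstrap-of-little-bags style) variance
#' estimate used by [predict.causal_forest()].
#'
#' @param trial a `trial_table` with complete covariates and both arms.
#' @param config a [forest_config()].
#' @param covariates covariate columns to use (default: all baseline
#'   covariates).
#' @return An object of class `causal_forest`.
#' @export
fit_causal_forest <- function(trial, config = forest_config(),
                              covariates = NULL) {
  if (nrow(trial) < 50) stopf("need at least 50 rows to fit a forest")
  check_trial_arms(trial$treatment)
  X <- encode_covariates(trial, covariates)
  Y <- as.numeric(trial$outcome)
  D <- as.integer(trial$treatment)
  n <- nrow(X)
  if (config$subsample_fraction * config$honesty_fraction * n <
      2 * config$min_leaf_per_arm) {
    stopf("subsample_fraction * honesty_fraction * n must be >= 2 * min_leaf_per_arm")
  }

  fit_pass <- function(Xp, seed) {
    .cf_fit_forest(Xp, Y, D, config$num_trees, config$subsample_fraction,
                   config$honesty_fraction, config$min_leaf_per_arm,
                   resolve_mtry(config$mtry, ncol(Xp)), config$max_depth,
                   config$ci_group_size, as.double(seed))
  }

  pass1 <- fit_pass(X, stage_seed(config$seed, "forest-pass1"))
  imp1 <- forest_importance(pass1, colnames(X), config$importance_decay)
  selected <- select_variables(imp1, config$importance_multiplier)
  if (length(selected) == 0) {
    selected <- names(which.max(imp1))
    warnf("importance filter removed all covariates; retaining '%s'", selected)
  }

  if (length(selected) == ncol(X)) {
    forest <- pass1
    Xf <- X
    two_pass <- FALSE
  } else {
    Xf <- X[, selected, drop = FALSE]
    forest <- fit_pass(Xf, stage_seed(config$seed, "forest-pass2"))
    two_pass <- TRUE
  }

  structure(list(forest = forest,
                 X = Xf,
                 covariate_names = colnames(Xf),
                 encoding = attr(X, "encoding"),
                 pass1_importance = imp1,
                 importance = forest_importance(forest, colnames(Xf),
                                                config$importance_decay),
                 selected = colnames(Xf),
                 two_pass = two_pass,
                 config = config,
                 n = n,
                 treatment = D,
                 outcome = Y,
                 ids = trial$id %||% seq_len(n),
                 propensity = attr(trial, "propensity") %||% 0.5),
            class = "causal_forest")
}

# out-of-bag indicator matrix (n x B): TRUE where the row was NOT in the
# tree's subsample
oob_matrix <- function(forest, n) {
  B <- forest$num_trees
  O <- matrix(TRUE, n, B)
  inbag <- forest$inbag
  for (b in seq_len(B)) O[inbag[[b]], b] <- FALSE
  O
}

# Aggregate per-tree leaf statistics into point estimates and paired
# half-sample variances. M: n x B matrix; U: usable-tree indicator.
aggregate_trees <- function(M, U) {
  M0 <- M
  M0[!U] <- 0
  nu <- rowSums(U)
  est <- ifelse(nu > 0, rowSums(M0) / nu, NA_real_)
  B <- ncol(M)
  odd <- seq(1, B - 1, by = 2)
  even <- odd + 1
  WG <- U[, odd, drop = FALSE] & U[, even, drop = FALSE]
  ng <- rowSums(WG)
  Gm <- (M0[, odd, drop = FALSE] + M0[, even, drop = FALSE]) / 2
  mg <- ifelse(ng > 0, rowSums(Gm * WG) / ng, NA_real_)
  varb <- ifelse(ng > 1, rowSums(WG * (Gm - mg)^2) / (ng - 1), NA_real_)
  wv <- ifelse(ng > 0, rowSums(
    WG * (M0[, odd, drop = FALSE] - M0[, even, drop = FALSE])^2 / 2) / ng,
    NA_real_)
  sigma2 <- pmax(varb - wv / 2, 0)
  list(estimate = est, sigma2 = sigma2, n_trees = nu)
}

# tau, mu0, mu1 point estimates (with OOB handling) plus tau variance
predict_components <- function(model, newdata = NULL) {
  if (is.null(newdata)) {
    X <- model$X
    U_oob <- oob_matrix(model$forest, nrow(X))
    oob <- TRUE
  } else {
    X <- encode_covariates(newdata, encoding = model$encoding)
    X <- X[, model$covariate_names, drop = FALSE]
    U_oob <- matrix(TRUE, nrow(X), model$forest$num_trees)
    oob <- FALSE
  }
  raw <- .cf_predict_raw(model$forest$trees, X)
  U <- U_oob & is.finite(raw$tau)
  agg <- aggregate_trees(raw$tau, U)
  m0 <- raw$mu0
  m0[!U] <- 0
  m1 <- raw$mu1
  m1[!U] <- 0
  nu <- rowSums(U)
  list(tau = agg$estimate,
       sigma2 = agg$sigma2,
       mu0 = ifelse(nu > 0, rowSums(m0) / nu, NA_real_),
       mu1 = ifelse(nu > 0, rowSums(m1) / nu, NA_real_),
       n_trees = agg$n_trees,
       oob = oob)
}

#' Predict conditional average treatment effects
#'
#' For training rows (`newdata = NULL`) predictions are out-of-bag: only
#' trees whose subsample excluded the row contribute. Standard errors come
#' from the paired half-sample ensemble variance: trees are grown in pairs
#' sharing a half-sample of the data, and the between-pair variance of pair
#' means, debiased by half the within-pair variance, estimates the sampling
#' variance of the forest estimate.
#'
#' @param object a `causal_forest`.
#' @param newdata optional data frame of covariates; default predicts
#'   out-of-bag for the training rows.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return A data frame of class `cate_estimate` with columns `id`,
#'   `tau_hat`, `se`, `ci_low`, `ci_high`, `oob`.
#' @export
predict.causal_forest <- function(object, newdata = NULL, level = 0.95, ...) {
  comp <- predict_components(object, newdata)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(comp$sigma2)
  ids <- if (is.null(newdata)) object$ids else newdata$id %||% seq_along(comp$tau)
  out <- data.frame(id = ids, tau_hat = comp$tau, se = se,
                    ci_low = comp$tau - z * se, ci_high = comp$tau + z * se,
                    oob = comp$oob)
  class(out) <- c("cate_estimate", "data.frame")
  out
}

#' @rdname predict.causal_forest
#' @param model a `causal_forest`.
#' @export
predict_cate <- function(model, newdata = NULL, level = 0.95) {
  predict(model, newdata = newdata, level = level)
}

forest_importance <- function(forest, covariate_names, decay = 2,
                              max_depth_considered = 4) {
  sc <- .cf_split_counts(forest$trees, length(covariate_names),
                         as.integer(max_depth_considered))
  w <- (seq_len(max_depth_considered))^(-decay)
  freq <- sc$counts
  tot <- sc$totals
  keep <- tot > 0
  raw <- as.numeric(freq[, keep, drop = FALSE] %*% w[keep])
  names(raw) <- covariate_names
  s <- sum(raw)
  if (s > 0) raw / s else raw
}

#' Depth-weighted split-frequency variable importance
#'
#' For depths 1..4, the fraction of depth-`d` splits made on each variable is
#' weighted by `d^(-decay)` and summed; scores are normalized to sum to 1.
#' A variable never split on scores 0.
#'
#' @param model a `causal_forest`.
#' @param decay depth-weight exponent (default: the model config's).
#' @return Named nonnegative numeric vector summing to 1.
#' @export
variable_importance <- function(model, decay = NULL) {
  stopifnot(inherits(model, "causal_forest"))
  decay <- decay %||% model$config$importance_decay
  forest_importance(model$forest, model$covariate_names, decay)
}

#' Select variables by importance threshold
#'
#' Retains names whose importance is at or above `multiplier` times the mean
#' importance; ties at the threshold are retained, so `multiplier = 0` keeps
#' everything.
#'
#' @param importance named nonnegative numeric vector.
#' @param multiplier nonnegative threshold multiplier.
#' @return Character vector of retained names (in input order).
#' @export
select_variables <- function(importance, multiplier = 1) {
  stopifnot(length(importance) > 0, !is.null(names(importance)),
            is_scalar_number(multiplier), multiplier >= 0)
  names(importance)[importance >= multiplier * mean(importance)]
}

#' @export
print.causal_forest <- function(x, ...) {
  cat(sprintf("Honest causal forest: %d trees, %d rows, %d covariate columns%s\n",
              x$forest$num_trees, x$n, length(x$covariate_names),
              if (x$two_pass) " (importance-filtered refit)" else " (single pass)"))
  top <- sort(x$importance, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("Top importance:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a causal forest as JSON
#'
#' Stores the tree arrays, subsample ids, configuration, importances and
#' training data, so the restored model predicts identically (including
#' out-of-bag predictions).
#'
#' @param model a `causal_forest`.
#' @param path JSON file path.
#' @return `write_forest_json` invisibly returns `path`; `read_forest_json`
#'   returns the restored `causal_forest`.
#' @export
write_forest_json <- function(model, path) {
  payload <- list(
    trees = model$forest$trees,
    inbag = model$forest$inbag,
    group = model$forest$group,
    num_trees = model$forest$num_trees,
    ci_group_size = model$forest$ci_group_size,
    X = lapply(seq_len(ncol(model$X)), function(j) model$X[, j]),
    covariate_names = model$covariate_names,
    encoding = model$encoding,
    pass1_importance = as.list(model$pass1_importance),
    importance = as.list(model$importance),
    selected = model$selected,
    two_pass = model$two_pass,
    config = unclass(model$config),
    n = model$n,
    treatment = model$treatment,
    outcome = model$outcome,
    ids = model$ids,
    propensity = model$propensity)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest_json
#' @export
read_forest_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  trees <- lapply(p$trees, function(tr) {
    lapply(tr, function(v) {
      if (is.list(v)) {
        # nulls (serialized NA, e.g. leaf thresholds) come back as NULL
        vapply(v, function(e) if (is.null(e)) NA_real_ else as.numeric(e), 0.0)
      } else {
        v
      }
    })
  })
  # jsonlite simplifies equal-length column lists to a (columns x rows) matrix
  X <- if (is.matrix(p$X)) t(p$X) else do.call(cbind, lapply(p$X, as.numeric))
  storage.mode(X) <- "double"
  colnames(X) <- p$covariate_names
  inbag <- if (is.matrix(p$inbag)) {
    lapply(seq_len(nrow(p$inbag)), function(b) as.integer(p$inbag[b, ]))
  } else {
    lapply(p$inbag, as.integer)
  }
  cfg <- p$config
  mtry <- cfg$mtry
  if (is.null(mtry) || length(mtry) == 0) mtry <- NULL
  config <- do.call(forest_config, c(
    cfg[setdiff(names(cfg), c("max_depth", "mtry"))],
    list(mtry = mtry,
         max_depth = if (cfg$max_depth < 0) Inf else cfg$max_depth)))
  structure(list(
    forest = list(trees = trees, inbag = inbag, group = p$group,
                  num_trees = p$num_trees, ci_group_size = p$ci_group_size),
    X = X,
    covariate_names = p$covariate_names,
    encoding = p$encoding,
    pass1_importance = unlist(p$pass1_importance),
    importance = unlist(p$importance),
    selected = p$selected,
    two_pass = p$two_pass,
    config = config,
    n = p$n,
    treatment = p$treatment,
    outcome = p$outcome,
    ids = p$ids,
    propensity = p$propensity), class = "causal_forest")
}
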
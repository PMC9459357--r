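#' Second-stage linear model for estimated CATEs
#'
#' Regresses the estimated individual treatment effects on the covariates
#' (with intercept). The intercept estimates the treatment effect independent
#' of the covariates; the slopes are the per-covariate differences between
#' the two potential-outcome regressions. Rank-deficient designs are handled
#' by dropping aliased columns with a warning naming them.
#'
#' @param cate a `cate_estimate` data frame (or numeric vector of CATEs).
#' @param covariates data frame of covariates (factors allowed).
#' @return A list of class `second_stage_fit` with `coefficients`,
#'   `r_squared`, `aliased`, and the underlying `fit`.
#' @export
second_stage_ols <- function(cate, covariates) {
  tau <- if (is.numeric(cate)) cate else cate$tau_hat
  stopifnot(length(tau) == nrow(covariates))
  if (nrow(unique(covariates)) < 2) {
    stopf("need at least 2 distinct covariate rows")
  }
  df <- cbind(data.frame(.tau = tau), covariates)
  fit <- lm(.tau ~ ., data = df)
  b <- coef(fit)
  aliased <- names(b)[is.na(b)]
  if (length(aliased) > 0) {
    warnf("dropping aliased columns: %s", paste(aliased, collapse = ", "))
  }
  structure(list(coefficients = b[!is.na(b)],
                 r_squared = summary(fit)$r.squared,
                 aliased = aliased, fit = fit),
            class = "second_stage_fit")
}

#' @export
predict.second_stage_fit <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = newdata))
}

# ---- normalized tree representation -------------------------------------
# nodes: data.frame(id, var (chr, NA at leaves), threshold, go_left_if
# ("lt" | "ge" | "le"), left, right (row ids), value (mean CATE), n)

normalize_rpart <- function(fit) {
  frame <- fit$frame
  node_num <- as.integer(rownames(frame))
  is_split <- frame$var != "<leaf>"
  # with maxcompete = maxsurrogate = 0 there is exactly one splits row per
  # internal node, in frame order
  splits <- fit$splits
  split_of <- integer(0)
  if (any(is_split)) split_of <- which(is_split)
  nodes <- data.frame(id = seq_len(nrow(frame)),
                      var = NA_character_, threshold = NA_real_,
                      go_left_if = NA_character_,
                      left = NA_integer_, right = NA_integer_,
                      value = frame$yval, n = frame$n,
                      stringsAsFactors = FALSE)
  si <- 0
  for (k in seq_len(nrow(frame))) {
    if (!is_split[k]) next
    si <- si + 1
    nodes$var[k] <- as.character(frame$var[k])
    nodes$threshold[k] <- splits[si, "index"]
    nodes$go_left_if[k] <- if (splits[si, "ncat"] < 0) "lt" else "ge"
    nodes$left[k] <- match(node_num[k] * 2L, node_num)
    nodes$right[k] <- match(node_num[k] * 2L + 1L, node_num)
  }
  nodes
}

normalize_ranger <- function(ti) {
  is_leaf <- ti$terminal
  data.frame(id = ti$nodeID + 1L,
             var = ifelse(is_leaf, NA_character_,
                          as.character(ti$splitvarName)),
             threshold = ifelse(is_leaf, NA_real_, ti$splitval),
             go_left_if = ifelse(is_leaf, NA_character_, "le"),
             left = ti$leftChild + 1L, right = ti$rightChild + 1L,
             value = ifelse(is_leaf, ti$prediction, NA_real_),
             n = NA_integer_, stringsAsFactors = FALSE)
}

new_subgroup_tree <- function(nodes, kind, cate, X, training_ids, extra) {
  leaf_id <- route_nodes(nodes, X)
  leaf_rows <- which(is.na(nodes$var))
  leaves <- data.frame(
    node = leaf_rows,
    path = vapply(leaf_rows, function(k) node_path(nodes, k), ""),
    n = vapply(leaf_rows, function(k) sum(leaf_id == k), 0L),
    mean_cate = vapply(leaf_rows, function(k) {
      if (any(leaf_id == k)) mean(cate[leaf_id == k]) else NA_real_
    }, 0.0),
    stringsAsFactors = FALSE)
  structure(c(list(nodes = nodes, kind = kind, leaves = leaves,
                   leaf_count = length(leaf_rows),
                   covariate_names = colnames(X),
                   training_ids = training_ids), extra),
            class = "subgroup_tree")
}

route_nodes <- function(nodes, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- 1L
    while (!is.na(nodes$var[k])) {
      xv <- X[i, nodes$var[k]]
      left <- switch(nodes$go_left_if[k],
                     lt = xv < nodes$threshold[k],
                     ge = xv >= nodes$threshold[k],
                     le = xv <= nodes$threshold[k])
      k <- if (left) nodes$left[k] else nodes$right[k]
    }
    out[i] <- k
  }
  out
}

node_path <- function(nodes, leaf) {
  # reconstruct the condition path from the root to `leaf`
  parent <- rep(NA_integer_, nrow(nodes))
  side <- rep(NA_character_, nrow(nodes))
  for (k in seq_len(nrow(nodes))) {
    if (!is.na(nodes$var[k])) {
      parent[nodes$left[k]] <- k
      side[nodes$left[k]] <- "L"
      parent[nodes$right[k]] <- k
      side[nodes$right[k]] <- "R"
    }
  }
  conds <- character(0)
  k <- leaf
  while (!is.na(parent[k])) {
    p <- parent[k]
    op <- switch(nodes$go_left_if[p], lt = c("<", ">="),
                 ge = c(">=", "<"), le = c("<=", ">"))
    cond <- sprintf("%s %s %.6g", nodes$var[p],
                    if (side[k] == "L") op[1] else op[2], nodes$threshold[p])
    conds <- c(cond, conds)
    k <- p
  }
  if (length(conds) == 0) "(root)" else paste(conds, collapse = " & ")
}

#' Pruned regression tree on estimated CATEs
#'
#' Grows a variance-reduction regression tree on the estimated individual
#' treatment effects and prunes it with complexity parameter `cp`: a split is
#' retained only if it reduces the tree's relative (root-error-relative)
#' error by at least `cp`. Covariates are one-hot encoded, so splits are
#' always numeric thresholds and fully deterministic.
#'
#' @param cate a `cate_estimate` (or numeric vector of CATEs).
#' @param covariates covariate data frame.
#' @param cp complexity parameter (>= 0); large values prune to the root.
#' @param minsplit,minbucket `rpart` size controls.
#' @param max_leaves optional cap: if set, `cp` is raised along the fitted
#'   complexity sequence until the tree has at most this many leaves.
#' @param weights optional case weights (e.g. inverse CATE variances); by
#'   default the fit is unweighted.
#' @param training_ids optional patient ids of the training rows (used to
#'   enforce honesty in [honest_subgroup_ates()]).
#' @return An object of class `subgroup_tree`.
#' @export
fit_pruned_cart <- function(cate, covariates, cp = 0.2, minsplit = 20,
                            minbucket = round(minsplit / 3), max_leaves = NULL,
                            weights = NULL, training_ids = NULL) {
  stopifnot(cp >= 0)
  tau <- if (is.numeric(cate)) cate else cate$tau_hat
  X <- encode_covariates(covariates,
                         covariates = names(covariates))
  df <- data.frame(.tau = tau, X, check.names = FALSE)
  ctrl <- rpart::rpart.control(cp = cp, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0,
                               minsplit = minsplit,
                               minbucket = max(1, minbucket))
  fit <- rpart::rpart(.tau ~ ., data = df, method = "anova", control = ctrl,
                      weights = weights)
  if (!is.null(max_leaves) && sum(fit$frame$var == "<leaf>") > max_leaves) {
    cpt <- fit$cptable
    ok <- cpt[, "nsplit"] <= max_leaves - 1
    cp_use <- min(cpt[ok, "CP"])
    fit <- rpart::prune(fit, cp = cp_use)
    cp <- cp_use
  }
  tree <- new_subgroup_tree(normalize_rpart(fit), "cart", tau, X,
                            training_ids,
                            list(cp = cp, encoding = attr(X, "encoding"),
                                 rpart_fit = fit))
  tree
}

#' Leaf membership of a subgroup tree
#' @param tree a `subgroup_tree`.
#' @param covariates covariate data frame to route.
#' @return Integer vector of leaf node row ids (matching `tree$leaves$node`).
#' @export
tree_leaf_membership <- function(tree, covariates) {
  X <- encode_covariates(covariates, covariates = names(covariates),
                         encoding = tree$encoding %||% NULL)
  missing_cols <- setdiff(tree$covariate_names, colnames(X))
  if (length(missing_cols) > 0) {
    stopf("covariates lack columns: %s", paste(missing_cols, collapse = ", "))
  }
  route_nodes(tree$nodes, X[, tree$covariate_names, drop = FALSE])
}

#' @export
predict.subgroup_tree <- function(object, newdata, ...) {
  leaf <- tree_leaf_membership(object, newdata)
  object$nodes$value[leaf]
}

#' Honest re-estimation of subgroup-tree leaf effects
#'
#' Routes held-out patients down a tree discovered on separate data and
#' re-estimates each leaf's effect as the AIPW group ATE over the held-out
#' rows in that leaf, with standard errors. Training-sample leaf means are
#' retained for comparison. Leaves receiving fewer than 2 held-out rows per
#' arm are flagged not estimable rather than erroring.
#'
#' @param tree a `subgroup_tree`.
#' @param scores `aipw_scores` for the held-out rows.
#' @param covariates held-out covariate data frame (same columns the tree
#'   was grown on).
#' @param level confidence level.
#' @return The tree with leaf columns `honest_n`, `honest_estimate`,
#'   `honest_se`, `honest_ci_low`, `honest_ci_high`, `estimable`.
#' @export
honest_subgroup_ates <- function(tree, scores, covariates, level = 0.95) {
  stopifnot(inherits(tree, "subgroup_tree"), inherits(scores, "aipw_scores"),
            nrow(scores) == nrow(covariates))
  if (!is.null(tree$training_ids) && !is.null(scores$id) &&
      length(intersect(tree$training_ids, scores$id)) > 0) {
    stopf("held-out rows overlap the tree's training rows; honesty violated")
  }
  leaf <- tree_leaf_membership(tree, covariates)
  z <- qnorm(1 - (1 - level) / 2)
  lv <- tree$leaves
  lv$honest_n <- 0L
  lv$honest_estimate <- NA_real_
  lv$honest_se <- NA_real_
  lv$honest_ci_low <- NA_real_
  lv$honest_ci_high <- NA_real_
  lv$estimable <- FALSE
  for (j in seq_len(nrow(lv))) {
    sel <- leaf == lv$node[j]
    lv$honest_n[j] <- sum(sel)
    n1 <- sum(scores$treatment[sel] == 1)
    n0 <- sum(scores$treatment[sel] == 0)
    if (n1 < 2 || n0 < 2) next
    g <- scores$gamma[sel]
    lv$honest_estimate[j] <- mean(g)
    lv$honest_se[j] <- sd(g) / sqrt(length(g))
    lv$honest_ci_low[j] <- lv$honest_estimate[j] - z * lv$honest_se[j]
    lv$honest_ci_high[j] <- lv$honest_estimate[j] + z * lv$honest_se[j]
    lv$estimable[j] <- TRUE
  }
  tree$leaves <- lv
  tree$honest <- TRUE
  tree
}

#' Best tree from a regression forest on estimated CATEs
#'
#' Fits a regression forest to the estimated CATEs with a minimum leaf size
#' `minN`, then returns the member tree whose predictions have the highest
#' R-squared against the forest's aggregate predictions (ties broken by the
#' lowest tree index) — the single tree most representative of the forest.
#'
#' @param cate a `cate_estimate` (or numeric vector).
#' @param covariates covariate data frame.
#' @param minN minimum number of observations a leaf must contain before
#'   further splitting (1 gives the deepest trees).
#' @param num_trees forest size.
#' @param seed integer seed.
#' @param training_ids optional ids of the training rows.
#' @return A `subgroup_tree` (kind `"ranger_best"`) with extra fields
#'   `r2_vs_forest`, `tree_index`, `minN` and per-tree diagnostics
#'   `all_r2`.
#' @export
best_tree <- function(cate, covariates, minN = 1, num_trees = 500, seed = 1L,
                      training_ids = NULL) {
  stopifnot(minN >= 1)
  tau <- if (is.numeric(cate)) cate else cate$tau_hat
  X <- encode_covariates(covariates, covariates = names(covariates))
  df <- data.frame(X, check.names = FALSE)
  rf <- ranger::ranger(x = df, y = tau, num.trees = num_trees,
                       min.node.size = minN, min.bucket = max(1, minN %/% 2),
                       seed = seed, num.threads = 1)
  pr <- predict(rf, data = df, predict.all = TRUE, num.threads = 1)$predictions
  forest_pred <- rowMeans(pr)
  sst <- sum((forest_pred - mean(forest_pred))^2)
  r2 <- if (sst > 0) {
    1 - colSums((pr - forest_pred)^2) / sst
  } else {
    rep(0, ncol(pr))
  }
  best <- which.max(r2)  # which.max returns the first (lowest) index on ties
  ti <- ranger::treeInfo(rf, best)
  nodes <- normalize_ranger(ti)
  tree <- new_subgroup_tree(nodes, "ranger_best", tau, X, training_ids,
                            list(minN = minN, tree_index = best,
                                 r2_vs_forest = r2[best], all_r2 = r2,
                                 encoding = attr(X, "encoding")))
  tree
}

#' Proportion of CATE variation explained
#'
#' `1 - SSE/SST`, with the total sum of squares taken about the mean of the
#' evaluation-set CATEs. Out-of-sample values can be negative. If the
#' evaluation CATEs are constant the quantity is undefined and `NA` is
#' returned with a warning.
#'
#' @param predictions numeric vector of predicted CATEs.
#' @param cate a `cate_estimate` (or numeric vector) to evaluate against.
#' @return A single numeric value (possibly `NA`).
#' @export
r2_explained <- function(predictions, cate) {
  tau <- if (is.numeric(cate)) cate else cate$tau_hat
  stopifnot(length(predictions) == length(tau))
  sst <- sum((tau - mean(tau))^2)
  if (sst <= 0) {
    warnf("evaluation CATEs are constant; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((tau - predictions)^2) / sst
}

#' @export
print.subgroup_tree <- function(x, ...) {
  cat(sprintf("Subgroup tree (%s): %d leaves\n", x$kind, x$leaf_count))
  cat(render_tree_text(x))
  invisible(x)
}

#' Indented plain-text rendering of a subgroup tree
#' @param tree a `subgroup_tree`.
#' @return A single string (lines joined by newlines).
#' @export
render_tree_text <- function(tree) {
  nodes <- tree$nodes
  leaves <- tree$leaves
  lines <- character(0)
  rec <- function(k, depth, label) {
    ind <- strrep("  ", depth)
    if (is.na(nodes$var[k])) {
      j <- match(k, leaves$node)
      extra <- if (!is.null(leaves$honest_estimate) &&
                   !is.na(leaves$honest_estimate[j])) {
        sprintf(", honest ATE %.4f (SE %.4f)", leaves$honest_estimate[j],
                leaves$honest_se[j])
      } else ""
      val <- leaves$mean_cate[j]
      lines <<- c(lines, sprintf("%s%s leaf: n=%s, mean CATE %s%s", ind, label,
                                 leaves$n[j],
                                 if (is.na(val)) "NA" else sprintf("%.4f", val),
                                 extra))
    } else {
      op <- switch(nodes$go_left_if[k], lt = c("<", ">="), ge = c(">=", "<"),
                   le = c("<=", ">"))
      lines <<- c(lines, sprintf("%s%s split on %s @ %.6g", ind, label,
                                 nodes$var[k], nodes$threshold[k]))
      rec(nodes$left[k], depth + 1,
          sprintf("[%s %s %.6g]", nodes$var[k], op[1], nodes$threshold[k]))
      rec(nodes$right[k], depth + 1,
          sprintf("[%s %s %.6g]", nodes$var[k], op[2], nodes$threshold[k]))
    }
  }
  rec(1L, 0, "(root)")
  paste(lines, collapse = "\n")
}

#' Serialize a subgroup tree to JSON (nested nodes) and its leaf table to CSV
#' @param tree a `subgroup_tree`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the tree.
#' @export
write_subgroup_tree <- function(tree, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    nest <- function(k) {
      nd <- tree$nodes[k, ]
      if (is.na(nd$var)) {
        j <- match(k, tree$leaves$node)
        as.list(tree$leaves[j, setdiff(names(tree$leaves), "node")])
      } else {
        list(var = nd$var, threshold = nd$threshold,
             go_left_if = nd$go_left_if,
             left = nest(nd$left), right = nest(nd$right))
      }
    }
    jsonlite::write_json(list(kind = tree$kind, leaf_count = tree$leaf_count,
                              cp = tree$cp %||% NULL,
                              minN = tree$minN %||% NULL,
                              root = nest(1L)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(csv_path)) {
    write.csv(tree$leaves, csv_path, row.names = FALSE)
  }
  invisible(tree)
}
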
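test_that("covariate encoding one-hots factors and reuses stored levels", {
  df <- data.frame(a = c(1.5, 2.5), b = factor(c("x", "y"), levels = c("x", "y", "z")))
  X <- encode_covariates(df, covariates = c("a", "b"))
  expect_identical(colnames(X), c("a", "b=x", "b=y", "b=z"))
  expect_equal(X[, "b=z"], c(0, 0))
  df2 <- data.frame(a = 1, b = "w")
  expect_warning(X2 <- encode_covariates(df2, encoding = attr(X, "encoding")),
                 "unseen")
  expect_equal(unname(X2[1, c("b=x", "b=y", "b=z")]), c(0, 0, 0))
  df3 <- df; df3$a[1] <- NA
  expect_error(encode_covariates(df3, covariates = c("a", "b")), "missing")
})

test_that("first split matches the exhaustive enumeration oracle", {
  for (s in 1:3) {
    tr <- tiny_trial(n = 36, seed = s, effect = 0.4)
    split_ids <- 1:18
    est_ids <- 19:36
    cfg <- forest_config(min_leaf_per_arm = 2, mtry = 99, seed = s)
    fit <- fit_causal_tree(tr, cfg, split_ids = split_ids, est_ids = est_ids)
    X <- encode_covariates(tr)
    orc <- split_oracle(X, tr$outcome, tr$treatment, split_ids, est_ids, 2)
    if (is.null(orc)) {
      expect_equal(fit$tree$var[1], -1L)
    } else {
      expect_equal(fit$tree$var[1] + 1L, orc$var)
      expect_equal(fit$tree$threshold[1], orc$threshold)
    }
  }
})

test_that("every leaf effect equals the recomputed honest difference in means", {
  tr <- tiny_trial(n = 40, seed = 4, effect = 0.4)
  split_ids <- 1:20
  est_ids <- 21:40
  fit <- fit_causal_tree(tr, forest_config(min_leaf_per_arm = 2, mtry = 99),
                         split_ids = split_ids, est_ids = est_ids)
  X <- encode_covariates(tr)
  leaf <- route_tree_r(fit$tree, X[est_ids, , drop = FALSE])
  for (k in which(fit$tree$var == -1L)) {
    ids <- est_ids[leaf == k]
    y <- tr$outcome[ids]
    d <- tr$treatment[ids]
    expect_identical(fit$tree$tau[k], mean(y[d == 1]) - mean(y[d == 0]))
    expect_identical(fit$tree$n1_est[k], sum(d == 1))
    expect_identical(fit$tree$n0_est[k], sum(d == 0))
  }
})

test_that("degenerate inputs give a single honest leaf", {
  tr <- tiny_trial(n = 24, seed = 5)
  for (v in c("x1", "x2", "x3")) tr[[v]] <- 1  # all covariates constant
  tr$g <- 0L
  split_ids <- 1:12
  est_ids <- 13:24
  fit <- fit_causal_tree(tr, forest_config(min_leaf_per_arm = 2, mtry = 99),
                         split_ids = split_ids, est_ids = est_ids)
  expect_equal(length(fit$tree$var), 1L)
  y <- tr$outcome[est_ids]
  d <- tr$treatment[est_ids]
  expect_equal(fit$tree$tau[1], mean(y[d == 1]) - mean(y[d == 0]))
})

test_that("the honest leaf estimator is the difference of arm means", {
  # leaf with treated outcomes {1, 0} and control outcomes {0, 0}
  tr <- as_trial_table(data.frame(
    id = 1:8, treatment = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L),
    outcome = c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L), x = rep(1, 8)))
  fit <- fit_causal_tree(tr, forest_config(min_leaf_per_arm = 1, mtry = 9),
                         split_ids = 1:4, est_ids = 5:8)
  expect_equal(fit$tree$tau[1], 0.5)
})

test_that("tree structure is honest: estimate-half outcomes never affect splits", {
  tr <- tiny_trial(n = 40, seed = 6, effect = 0.4)
  split_ids <- 1:20
  est_ids <- 21:40
  cfg <- forest_config(min_leaf_per_arm = 2, mtry = 99, seed = 1)
  f1 <- fit_causal_tree(tr, cfg, split_ids = split_ids, est_ids = est_ids)
  tr2 <- tr
  tr2$outcome[est_ids] <- 1L - tr2$outcome[est_ids]
  f2 <- fit_causal_tree(tr2, cfg, split_ids = split_ids, est_ids = est_ids)
  expect_identical(f1$tree$var, f2$tree$var)
  expect_identical(f1$tree$threshold, f2$tree$threshold)
})

test_that("forest fitting is seeded and deterministic", {
  tr <- generate_trial(design_step_cate(300, seed = 2))
  cfg <- forest_config(num_trees = 30, seed = 5)
  m1 <- fit_causal_forest(tr, cfg)
  m2 <- fit_causal_forest(tr, cfg)
  expect_identical(predict(m1)$tau_hat, predict(m2)$tau_hat)
  m3 <- fit_causal_forest(tr, forest_config(num_trees = 30, seed = 6))
  expect_false(identical(predict(m1)$tau_hat, predict(m3)$tau_hat))
})

test_that("constant covariates give every patient the same prediction", {
  tr <- tiny_trial(n = 120, seed = 7)
  for (v in c("x1", "x2", "x3")) tr[[v]] <- 2
  tr$g <- 1L
  m <- fit_causal_forest(tr, forest_config(num_trees = 20, seed = 1))
  pr <- predict(m, tr)
  expect_equal(length(unique(pr$tau_hat)), 1L)
})

test_that("predictions are invariant under row permutation", {
  tr <- generate_trial(design_step_cate(200, seed = 8, noise_covariates = 2))
  m <- fit_causal_forest(tr, forest_config(num_trees = 30, seed = 2))
  perm <- rev(seq_len(nrow(tr)))
  pr <- predict(m, tr)
  pr_perm <- predict(m, tr[perm, ])
  expect_equal(pr_perm$tau_hat, pr$tau_hat[perm])
})

test_that("confidence intervals are centred with 1.96-SE half-width", {
  tr <- generate_trial(design_step_cate(400, seed = 3))
  m <- fit_causal_forest(tr, forest_config(num_trees = 100, seed = 2))
  ce <- predict(m)
  expect_true(all(ce$ci_low <= ce$tau_hat & ce$tau_hat <= ce$ci_high))
  expect_equal(ce$ci_high - ce$tau_hat, qnorm(0.975) * ce$se, tolerance = 1e-10)
})

test_that("variable importance is a normalized depth-weighted split frequency", {
  tr <- generate_trial(design_modifier_retention(800, seed = 4))
  tr$never_used <- 0  # constant column can never be split on
  attr(tr, "covariates") <- c(baseline_covariates(tr), "never_used")
  m <- fit_causal_forest(tr, forest_config(num_trees = 60, seed = 3,
                                           importance_multiplier = 0))
  imp <- variable_importance(m)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  expect_equal(unname(imp["never_used"]), 0)
})

test_that("importance filtering selects above a multiple of the mean", {
  imp <- c(a = 0.5, b = 0.3, c = 0.1, d = 0.1)
  expect_identical(select_variables(imp, 1), c("a", "b"))
  expect_identical(select_variables(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25), 1),
                   c("a", "b", "c", "d"))
  expect_identical(select_variables(imp, 0), names(imp))
  # retained set grows as the multiplier shrinks
  s_small <- select_variables(imp, 0.2)
  s_big <- select_variables(imp, 1)
  expect_true(all(s_big %in% s_small))
})

test_that("two-pass refit retains importance audit; multiplier 0 is single-pass", {
  tr <- generate_trial(design_modifier_retention(600, seed = 9))
  m <- fit_causal_forest(tr, forest_config(num_trees = 60, seed = 1))
  expect_true(m$two_pass)
  expect_true(length(m$selected) < length(m$pass1_importance))
  expect_true(all(m$selected %in% names(m$pass1_importance)))
  m0 <- fit_causal_forest(tr, forest_config(num_trees = 60, seed = 1,
                                            importance_multiplier = 0))
  expect_false(m0$two_pass)
  expect_equal(length(m0$selected), length(m0$pass1_importance))
  # an extreme multiplier falls back to the single most important covariate
  expect_warning(
    m10 <- fit_causal_forest(tr, forest_config(num_trees = 60, seed = 1,
                                               importance_multiplier = 10)),
    "retaining")
  expect_equal(length(m10$selected), 1L)
})

test_that("forest models survive a JSON round trip", {
  tr <- generate_trial(design_step_cate(200, seed = 2))
  m <- fit_causal_forest(tr, forest_config(num_trees = 20, seed = 3))
  path <- file.path(tempdir(), "forest.json")
  write_forest_json(m, path)
  m2 <- read_forest_json(path)
  expect_equal(predict(m)$tau_hat, predict(m2)$tau_hat, tolerance = 1e-12)
  expect_equal(m$importance, m2$importance, tolerance = 1e-12)
  unlink(path)
})

test_that("a genuine strong modifier is retained by the importance filter", {
  kept <- vapply(1:10, function(s) {
    tr <- generate_trial(design_modifier_retention(2000, seed = 400 + s))
    m <- fit_causal_forest(tr, forest_config(num_trees = 300, seed = s))
    "modifier" %in% m$selected
  }, TRUE)
  expect_gte(mean(kept), 0.9)
})

test_that("estimation error shrinks with sample size (consistency)", {
  err <- vapply(c(1000, 4000), function(n) {
    mean(vapply(1:3, function(s) {
      tr <- generate_trial(design_step_cate(n, seed = 500 + s))
      m <- fit_causal_forest(tr, forest_config(num_trees = 300, seed = s))
      mean(abs(predict(m)$tau_hat - tr$true_tau))
    }, 0.0))
  }, 0.0)
  expect_lt(err[2], err[1])
})
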
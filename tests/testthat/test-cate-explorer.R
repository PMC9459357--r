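test_that("second-stage OLS recovers an exactly linear CATE surface", {
  set.seed(1)
  covs <- data.frame(a = rnorm(100), b = rnorm(100))
  tau <- 0.5 - 0.3 * covs$a + 0.1 * covs$b
  fit <- second_stage_ols(tau, covs)
  expect_equal(unname(fit$coefficients),
               c(0.5, -0.3, 0.1), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  # constant CATE: intercept only
  fit0 <- second_stage_ols(rep(0.2, 100), covs)
  expect_equal(unname(fit0$coefficients[1]), 0.2, tolerance = 1e-10)
  expect_equal(unname(fit0$coefficients[-1]), c(0, 0), tolerance = 1e-10)
})

test_that("second-stage OLS equals the normal-equations solution", {
  set.seed(2)
  covs <- data.frame(a = rnorm(60), b = runif(60))
  tau <- rnorm(60)
  fit <- second_stage_ols(tau, covs)
  Xd <- cbind(1, as.matrix(covs))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% tau)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("aliased columns are dropped with a warning naming them", {
  set.seed(3)
  covs <- data.frame(a = rnorm(50))
  covs$b <- 2 * covs$a
  expect_warning(fit <- second_stage_ols(rnorm(50), covs), "b")
  expect_false("b" %in% names(fit$coefficients))
})

test_that("a noise-free binary step is found by a single split", {
  set.seed(4)
  covs <- data.frame(g = rbinom(200, 1, 0.5), z = rnorm(200))
  tau <- ifelse(covs$g == 1, -0.06, -0.02)
  tree <- fit_pruned_cart(tau, covs, cp = 0.2, minsplit = 10)
  expect_equal(tree$leaf_count, 2L)
  expect_equal(tree$nodes$var[1], "g")
  expect_equal(sort(tree$leaves$mean_cate), c(-0.06, -0.02), tolerance = 1e-12)
})

test_that("complexity pruning behaves at its boundaries", {
  set.seed(5)
  covs <- data.frame(a = rbinom(40, 1, 0.5), b = rbinom(40, 1, 0.5))
  tau <- 0.1 * covs$a - 0.2 * covs$b + 0.05 * covs$a * covs$b
  # cp = 1: maximal pruning to the root
  t1 <- fit_pruned_cart(tau, covs, cp = 1)
  expect_equal(t1$leaf_count, 1L)
  # cp = 0, tiny n: leaves reproduce the covariate cross-classification
  t0 <- fit_pruned_cart(tau, covs, cp = 0, minsplit = 2, minbucket = 1)
  cells <- unique(data.frame(covs, tau))
  expect_equal(t0$leaf_count, nrow(cells))
  # in-sample fit improves monotonically as cp decreases
  covs2 <- data.frame(a = rnorm(300), b = rnorm(300))
  tau2 <- 0.2 * sign(covs2$a) * sign(covs2$b) + rnorm(300, 0, 0.05)
  r2 <- vapply(c(0.5, 0.1, 0.01), function(cp) {
    tr <- fit_pruned_cart(tau2, covs2, cp = cp, minsplit = 10)
    r2_explained(predict(tr, covs2), tau2)
  }, 0.0)
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("leaf caps raise the complexity along the fitted sequence", {
  set.seed(6)
  covs <- data.frame(a = rnorm(400), b = rnorm(400), c = rnorm(400))
  tau <- 0.3 * sign(covs$a) + 0.2 * sign(covs$b) + rnorm(400, 0, 0.02)
  tree <- fit_pruned_cart(tau, covs, cp = 0.001, minsplit = 5,
                          max_leaves = 10)
  expect_lte(tree$leaf_count, 10)
})

test_that("honest leaf re-estimation uses only held-out AIPW scores", {
  tr <- generate_trial(design_step_cate(2000, seed = 31))
  m <- fit_causal_forest(tr, forest_config(num_trees = 200, seed = 7))
  sc <- aipw_scores(m, tr)
  idx_a <- 1:1000
  idx_b <- 1001:2000
  covs <- as.data.frame(tr)[, baseline_covariates(tr), drop = FALSE]
  tree <- fit_pruned_cart(tr$true_tau[idx_a], covs[idx_a, , drop = FALSE],
                          cp = 0.2, minsplit = 10,
                          training_ids = tr$id[idx_a])
  sc_b <- sc[idx_b, ]
  attr(sc_b, "propensity") <- attr(sc, "propensity")
  ht <- honest_subgroup_ates(tree, sc_b, covs[idx_b, , drop = FALSE])
  expect_true(all(ht$leaves$estimable))
  # root-only tree: the honest estimate is the held-out overall ATE
  root <- fit_pruned_cart(tr$true_tau[idx_a], covs[idx_a, , drop = FALSE],
                          cp = 1, training_ids = tr$id[idx_a])
  hr <- honest_subgroup_ates(root, sc_b, covs[idx_b, , drop = FALSE])
  expect_equal(hr$leaves$honest_estimate, mean(sc_b$gamma), tolerance = 1e-12)
  # overlapping rows violate honesty
  expect_error(honest_subgroup_ates(tree, sc, covs), "honesty")
})

test_that("leaves starved of held-out data are flagged, not errors", {
  set.seed(8)
  covs_a <- data.frame(g = rbinom(100, 1, 0.5))
  tree <- fit_pruned_cart(ifelse(covs_a$g == 1, -0.5, 0.5), covs_a, cp = 0.1,
                          minsplit = 5, training_ids = 1:100)
  # held-out data where one leaf receives a single arm only
  held <- data.frame(id = 201:260, gamma = rnorm(60), tau_oob = 0,
                     mu0 = 0, mu1 = 0,
                     treatment = c(rep(1, 30), rep(0, 30)))
  class(held) <- c("aipw_scores", "data.frame")
  covs_b <- data.frame(g = c(rep(1, 30), rep(0, 30)))
  ht <- honest_subgroup_ates(tree, held, covs_b)
  expect_false(any(ht$leaves$estimable))
  expect_true(all(is.na(ht$leaves$honest_estimate)))
})

test_that("the best tree is the forest member most like the ensemble", {
  set.seed(9)
  covs <- data.frame(a = rnorm(300), b = rbinom(300, 1, 0.4))
  tau <- -0.05 * covs$b + 0.02 * (covs$a > 0) + rnorm(300, 0, 0.01)
  bt <- best_tree(tau, covs, minN = 20, num_trees = 60, seed = 5)
  expect_equal(bt$r2_vs_forest, max(bt$all_r2))
  expect_equal(bt$tree_index, which.max(bt$all_r2))
  # boundary: minN = n forces root-only trees
  bt_root <- best_tree(tau, covs, minN = 300, num_trees = 20, seed = 5)
  expect_equal(bt_root$leaf_count, 1L)
})

test_that("best-tree depth responds monotonically to the leaf-size ladder", {
  ladder <- c(1, 50, 100, 200)
  ok <- vapply(1:10, function(s) {
    set.seed(700 + s)
    covs <- data.frame(a = rnorm(400), b = rbinom(400, 1, 0.4))
    tau <- -0.05 * covs$b + 0.03 * covs$a + rnorm(400, 0, 0.02)
    leaves <- vapply(ladder, function(mn) {
      best_tree(tau, covs, minN = mn, num_trees = 30, seed = s)$leaf_count
    }, 0L)
    all(diff(leaves) <= 0)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("explained-variation follows its closed form", {
  tau <- c(1, 2, 3, 4, 5)
  expect_equal(r2_explained(tau, tau), 1)
  expect_equal(r2_explained(rep(mean(tau), 5), tau), 0)
  pred <- c(1.2, 2.1, 2.7, 4.4, 4.9)
  expect_equal(r2_explained(pred, tau),
               1 - sum((tau - pred)^2) / sum((tau - mean(tau))^2),
               tolerance = 1e-12)
  expect_warning(r2_0 <- r2_explained(rep(1, 3), rep(2, 3)), "undefined")
  expect_true(is.na(r2_0))
})

test_that("flexible trees out-explain coarse trees and the linear model", {
  # non-linear CATE with an interaction: deepest best tree >= coarse best
  # tree >= linear model, in explained variation
  set.seed(11)
  n <- 1000
  covs <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
                     z = rnorm(n))
  tau <- -0.08 * covs$a * covs$b + rnorm(n, 0, 0.01)
  r2_of <- function(pred) r2_explained(pred, tau)
  deep <- r2_of(predict(best_tree(tau, covs, minN = 1, num_trees = 50,
                                  seed = 3), covs))
  coarse <- r2_of(predict(best_tree(tau, covs, minN = 200, num_trees = 50,
                                    seed = 3), covs))
  ols <- r2_of(predict(second_stage_ols(tau, covs), covs))
  expect_gte(deep, coarse - 1e-9)
  expect_gte(coarse, ols - 1e-9)
})

test_that("subgroup trees serialize to JSON and a leaf CSV", {
  set.seed(12)
  covs <- data.frame(g = rbinom(120, 1, 0.5), z = rnorm(120))
  tau <- ifelse(covs$g == 1, -0.06, -0.02) + rnorm(120, 0, 0.001)
  tree <- fit_pruned_cart(tau, covs, cp = 0.2, minsplit = 10)
  jp <- file.path(tempdir(), "tree.json")
  cp <- file.path(tempdir(), "leaves.csv")
  write_subgroup_tree(tree, jp, cp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$leaf_count, tree$leaf_count)
  expect_true(!is.null(parsed$root$var) || !is.null(parsed$root$n))
  leaves <- read.csv(cp)
  expect_equal(nrow(leaves), tree$leaf_count)
  txt <- render_tree_text(tree)
  expect_match(txt, "split on g")
  unlink(c(jp, cp))
})
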
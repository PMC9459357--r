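# trial with known (G, D) cell event probabilities; the subgroup indicator
# is stored in column `g`
cell_trial <- function(n, probs, seed = 1) {
  hteforest:::with_seed(seed, {
    g <- rbinom(n, 1, 0.5)
    d <- rbinom(n, 1, 0.5)
    p <- probs[cbind(g + 1, d + 1)]
    as_trial_table(data.frame(id = seq_len(n), treatment = d,
                              outcome = rbinom(n, 1, p), g = g,
                              x = rnorm(n)),
                   covariates = c("g", "x"))
  })
}

test_that("the saturated logistic fit reproduces empirical cell log-odds", {
  probs <- rbind(c(0.30, 0.22), c(0.45, 0.28))  # rows G, cols D
  tr <- cell_trial(4000, probs, seed = 2)
  fit <- fit_subgroup_model(tr, tr$g)
  b <- fit$coefficients
  emp_logit <- function(g, d) {
    qlogis(mean(tr$outcome[tr$g == g & tr$treatment == d]))
  }
  expect_equal(b[["intercept"]], emp_logit(0, 0), tolerance = 1e-8)
  expect_equal(b[["intercept"]] + b[["beta_G"]], emp_logit(1, 0),
               tolerance = 1e-8)
  expect_equal(b[["intercept"]] + b[["alpha1"]], emp_logit(0, 1),
               tolerance = 1e-8)
  expect_equal(sum(b), emp_logit(1, 1), tolerance = 1e-8)
})

test_that("no-interaction truth yields a near-zero interaction estimate", {
  probs <- rbind(c(0.35, 0.30), c(0.45, 0.40))  # same D-effect in both groups
  tr <- cell_trial(20000, probs, seed = 3)
  fit <- fit_subgroup_model(tr, tr$g)
  expect_lt(abs(fit$coefficients[["alpha2"]]), 0.1)
})

test_that("an all-event or no-event cell raises a separation error", {
  tr <- as_trial_table(data.frame(
    id = 1:40,
    treatment = rep(c(0L, 1L), 20),
    outcome = c(rep(0L, 20), rep(c(0L, 1L), 10)),
    x = rnorm(40)), covariates = "x")
  grp <- rep(c(0, 1), each = 20)
  # cell G=0 has no events in either arm
  expect_error(fit_subgroup_model(tr, grp), "separation")
})

test_that("recycled predictions on the saturated model equal cell contrasts", {
  probs <- rbind(c(0.30, 0.22), c(0.45, 0.28))
  tr <- cell_trial(3000, probs, seed = 4)
  fit <- fit_subgroup_model(tr, tr$g)
  gc <- gcomp_effects(fit, tr)
  # total effect for the subgroup = raw risk difference among its members
  raw_rd <- mean(tr$outcome[tr$g == 1 & tr$treatment == 1]) -
    mean(tr$outcome[tr$g == 1 & tr$treatment == 0])
  expect_equal(gc$total_effect, raw_rd, tolerance = 1e-10)
  expect_true(all(gc$predictions >= 0 & gc$predictions <= 1))
})

test_that("the identity-link interaction contrast equals alpha2 exactly", {
  probs <- rbind(c(0.30, 0.22), c(0.45, 0.28))
  tr <- cell_trial(3000, probs, seed = 5)
  fit <- fit_subgroup_model(tr, tr$g, link = "identity")
  gc <- gcomp_effects(fit, tr)
  expect_equal(gc$interaction_effect, fit$coefficients[["alpha2"]],
               tolerance = 1e-12)
})

test_that("a model with null treatment coefficients gives null effects", {
  model <- structure(list(coefficients = c(intercept = -0.5, beta_G = 0.3,
                                           alpha1 = 0, alpha2 = 0),
                          link = "logit", converged = TRUE),
                     class = "subgroup_logistic_model")
  tr <- cell_trial(100, rbind(c(0.3, 0.3), c(0.3, 0.3)), seed = 6)
  gc <- gcomp_effects(model, tr)
  expect_equal(gc$total_effect, 0)
  expect_equal(gc$interaction_effect, 0)
})

test_that("the bootstrap is seeded and degenerates correctly", {
  tr <- cell_trial(400, rbind(c(0.3, 0.25), c(0.4, 0.3)), seed = 7)
  stat <- function(t) mean(t$outcome[t$treatment == 1]) -
    mean(t$outcome[t$treatment == 0])
  b1 <- bootstrap_ci(stat, tr, B_boot = 200, seed = 9)
  b2 <- bootstrap_ci(stat, tr, B_boot = 200, seed = 9)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  # constant outcome: the statistic never varies
  tr0 <- tr
  tr0$outcome <- rep(1L, nrow(tr0))
  b0 <- bootstrap_ci(function(t) mean(t$outcome), tr0, B_boot = 100, seed = 1)
  expect_equal(unname(b0$se), 0)
})

test_that("bootstrap SE approximates the analytic difference-in-proportions SE", {
  probs <- rbind(c(0.35, 0.25), c(0.35, 0.25))
  tr <- cell_trial(5000, probs, seed = 8)
  stat <- function(t) mean(t$outcome[t$treatment == 1]) -
    mean(t$outcome[t$treatment == 0])
  bt <- bootstrap_ci(stat, tr, B_boot = 400, seed = 2)
  n1 <- sum(tr$treatment == 1)
  n0 <- sum(tr$treatment == 0)
  p1 <- mean(tr$outcome[tr$treatment == 1])
  p0 <- mean(tr$outcome[tr$treatment == 0])
  analytic <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  expect_lt(abs(unname(bt$se) - analytic) / analytic, 0.15)
})

test_that("null bootstrap intervals have near-nominal coverage", {
  # homogeneous null risk difference; 95% percentile CIs should cover 0
  # in roughly 93-97% of replicates
  stat <- function(t) mean(t$outcome[t$treatment == 1]) -
    mean(t$outcome[t$treatment == 0])
  covered <- vapply(1:500, function(s) {
    tr <- cell_trial(250, rbind(c(0.35, 0.35), c(0.35, 0.35)),
                     seed = 1000 + s)
    bt <- bootstrap_ci(stat, tr, B_boot = 200, seed = s)
    bt$ci_low <= 0 && 0 <= bt$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("subgroup recycled predictions collapse over the partition", {
  tr <- cell_trial(2500, rbind(c(0.32, 0.24), c(0.44, 0.30)), seed = 10)
  fit <- fit_subgroup_model(tr, tr$g)
  gc <- gcomp_effects(fit, tr)
  n1 <- sum(tr$g == 1)
  n0 <- sum(tr$g == 0)
  pooled <- (n1 * gc$total_effect + n0 * gc$total_effect_complement) /
    (n1 + n0)
  direct <- (n1 * (mean(tr$outcome[tr$g == 1 & tr$treatment == 1]) -
                     mean(tr$outcome[tr$g == 1 & tr$treatment == 0])) +
               n0 * (mean(tr$outcome[tr$g == 0 & tr$treatment == 1]) -
                       mean(tr$outcome[tr$g == 0 & tr$treatment == 0]))) /
    (n1 + n0)
  expect_equal(pooled, direct, tolerance = 1e-10)
})
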
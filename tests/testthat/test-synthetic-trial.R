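test_that("default covariate marginals match the emulated baseline table", {
  tr <- generate_trial(simulation_config(n = 10000, seed = 7))
  expect_true(abs(mean(tr$chronic_hypertension) - 0.458) < 0.02)
  expect_true(abs(mean(tr$sepsis3 == "septic_shock") - 0.483) < 0.02)
  expect_true(all(tr$age >= 65))
  expect_true(abs(mean(tr$male) - 0.566) < 0.02)
  expect_true(all(tr$icnarc_risk > 0 & tr$icnarc_risk < 1))
})

test_that("generation is deterministic and potential outcomes are consistent", {
  cfg <- simulation_config(n = 500, seed = 11)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(t1$outcome,
                   t1$treatment * t1$y1 + (1L - t1$treatment) * t1$y0)
  expect_false(anyNA(t1$treatment))
  expect_false(anyNA(t1$outcome))
  # regenerating from the stored configuration reproduces the outcomes
  t3 <- generate_trial(attr(t1, "config"))
  expect_identical(t1$outcome, t3$outcome)
})

test_that("null treatment-effect construction gives a null arm difference", {
  cfg <- simulation_config(n = 50000, seed = 3, cate_fn = cate_constant(0))
  tr <- generate_trial(cfg)
  d <- mean(tr$outcome[tr$treatment == 1]) - mean(tr$outcome[tr$treatment == 0])
  se <- sqrt(var(tr$outcome) * (1 / sum(tr$treatment) +
                                  1 / sum(1 - tr$treatment)))
  expect_lt(abs(d), 4 * se)
})

test_that("arm sizes stay near the design propensity across seeds", {
  n <- 2000
  imbalance <- vapply(1:20, function(s) {
    tr <- suppressWarnings(generate_trial(simulation_config(n = n, seed = s)))
    abs(sum(tr$treatment) - n / 2)
  }, 0.0)
  expect_true(all(imbalance <= 4 * sqrt(n)))
})

test_that("empirical ATE converges to the mean of the true CATE", {
  cfg <- design_step_cate(50000, seed = 5)
  tr <- generate_trial(cfg)
  emp <- mean(tr$y1) - mean(tr$y0)
  mc_se <- sqrt((var(tr$y1) + var(tr$y0)) / nrow(tr))
  expect_lt(abs(emp - mean(tr$true_tau)), 3 * mc_se)
})

test_that("true_group_ate returns construction truth and matches re-evaluation", {
  tr <- generate_trial(design_step_cate(2000, seed = 9))
  hyp <- tr$chronic_hypertension == 1
  expect_equal(true_group_ate(tr, hyp), -0.06)
  expect_equal(true_group_ate(tr, !hyp), -0.02)
  expect_equal(true_group_ate(tr, rep(TRUE, nrow(tr))), mean(tr$true_tau))
  orc <- oracle_risks(tr)
  expect_equal(mean(tr$true_tau), mean(orc$mu1 - orc$mu0), tolerance = 1e-12)
  tr$true_tau <- NULL
  expect_error(true_group_ate(tr, hyp), "synthetic")
})

test_that("missingness injection is MCAR on covariates only", {
  tr <- suppressWarnings(generate_trial(simulation_config(n = 3000, seed = 13)))
  expect_identical(inject_missingness(tr, 0), tr)
  covs <- baseline_covariates(tr)
  t1 <- inject_missingness(tr, 1, seed = 2)
  expect_true(all(vapply(covs, function(v) all(is.na(t1[[v]])), TRUE)))
  expect_false(anyNA(t1$outcome))
  expect_false(anyNA(t1$treatment))
  t2 <- inject_missingness(tr, 0.001, seed = 2)
  n_cells <- nrow(tr) * length(covs)
  n_miss <- sum(is.na(t2[, covs]))
  expect_lt(abs(n_miss - 0.001 * n_cells), 4 * sqrt(0.001 * n_cells) + 1)
  expect_error(inject_missingness(tr, 1.5), "rate")
})

test_that("invalid covariate specifications name the offending covariate", {
  bad <- list(list(name = "frac", kind = "binary", p = 1.4))
  expect_error(simulation_config(covariate_spec = bad), "frac")
  bad2 <- list(list(name = "cat", kind = "categorical",
                    levels = c("a", "b"), probs = c(0.9, 0.6)))
  expect_error(simulation_config(covariate_spec = bad2), "cat")
})

test_that("quintile groups assign boundary ties to the lower quintile", {
  x <- c(rep(1, 30), rep(2, 30), rep(3, 40))
  q <- quintile_groups(x)
  # 2 is both the upper bound of one quintile interval and present in the
  # next; all 2s must land in the lower of the two groups
  expect_equal(length(unique(q[x == 2])), 1L)
  expect_lt(unique(as.integer(q[x == 2])), unique(as.integer(q[x == 3])))
  q2 <- quintile_groups(rnorm(500))
  expect_equal(length(levels(q2)), 5)
})

test_that("trial tables round-trip through CSV with sidecar", {
  tr <- generate_trial(simulation_config(n = 120, seed = 17,
                                         missing_rate = 0.02))
  path <- file.path(tempdir(), "trial.csv")
  write_trial(tr, path)
  tr2 <- read_trial(path)
  expect_equal(as.data.frame(tr)$outcome, tr2$outcome)
  expect_identical(levels(tr$sepsis3), levels(tr2$sepsis3))
  expect_equal(baseline_covariates(tr), baseline_covariates(tr2))
  expect_equal(tr$age, tr2$age, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
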
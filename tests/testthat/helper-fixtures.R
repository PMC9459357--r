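# Small deterministic fixtures and independent oracles used across the suite.

# A tiny trial table with jittered continuous covariates (ties improbable)
# and a binary covariate, balanced arms.
tiny_trial <- function(n = 32, seed = 1, p_covs = 3, effect = 0) {
  withr_seed <- function(expr) hteforest:::with_seed(seed, expr)
  withr_seed({
    X <- as.data.frame(matrix(rnorm(n * p_covs), n, p_covs))
    names(X) <- paste0("x", seq_len(p_covs))
    X$g <- rbinom(n, 1, 0.5)
    D <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
    p <- 0.4 + effect * D * X$g
    Y <- rbinom(n, 1, pmin(pmax(p, 0.05), 0.95))
    as_trial_table(cbind(data.frame(id = seq_len(n), treatment = D,
                                    outcome = Y), X))
  })
}

# Exhaustive enumeration of every (variable, threshold) candidate under the
# tree's split criterion and size constraints; independent of the C++ path.
split_oracle <- function(X, Y, D, split_ids, est_ids, min_leaf) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[split_ids, j]
    xe <- X[est_ids, j]
    ux <- sort(unique(xs))
    if (length(ux) < 2) next
    thrs <- (ux[-length(ux)] + ux[-1]) / 2
    for (t in thrs) {
      lo <- max(ux[ux < t]); hi <- min(ux[ux >= t])
      if (!(t > lo && t <= hi)) next
      sl <- split_ids[xs < t]; sr <- split_ids[xs >= t]
      el <- est_ids[xe < t]; er <- est_ids[xe >= t]
      counts <- c(sum(D[sl] == 1), sum(D[sl] == 0),
                  sum(D[sr] == 1), sum(D[sr] == 0),
                  sum(D[el] == 1), sum(D[el] == 0),
                  sum(D[er] == 1), sum(D[er] == 0))
      if (any(counts < min_leaf)) next
      tau <- function(ids) {
        mean(Y[ids][D[ids] == 1]) - mean(Y[ids][D[ids] == 0])
      }
      crit <- length(sl) * tau(sl)^2 + length(sr) * tau(sr)^2
      if (is.null(best) || crit > best$crit + 1e-12) {
        best <- list(var = j, threshold = t, crit = crit)
      }
    }
  }
  best
}

# route rows through the raw C++ node arrays (0-based child indices)
route_tree_r <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    k <- 1L
    while (tree$var[k] >= 0) {
      k <- if (X[i, tree$var[k] + 1] < tree$threshold[k]) {
        tree$left[k] + 1L
      } else {
        tree$right[k] + 1L
      }
    }
    k
  }, 1L)
}

# oracle (clipped) potential-outcome risks recomputed from the generating
# functions of a synthetic trial
oracle_risks <- function(trial) {
  config <- attr(trial, "config")
  data <- as.data.frame(trial)[, baseline_covariates(trial), drop = FALSE]
  clip <- function(p) pmin(pmax(p, 0.001), 0.999)
  p0 <- clip(config$baseline_risk(data))
  p1 <- clip(config$baseline_risk(data) + config$cate_fn(data))
  list(mu0 = p0, mu1 = p1, tau = p1 - p0)
}
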
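#' Pipeline configuration
#'
#' @param input a [simulation_config()] (the trial is generated) or a path to
#'   a trial CSV written by [write_trial()].
#' @param subgroup_vars covariate names to report subgroup effects for;
#'   continuous variables are split into sample quintiles (ties to the lower
#'   quintile). Default: the seven prespecified critical-care subgroups (age,
#'   chronic hypertension, chronic heart failure, atherosclerotic disease,
#'   predicted risk of death, Sepsis-3 category, vasopressor type) plus nine
#'   additional ones (sex, ethnicity, prior dependency, arterial pressure,
#'   admission source, APACHE II, ICNARC physiology, prior CPR, SOFA).
#' @param forest a [forest_config()].
#' @param cp complexity parameter for the pruned CART summary.
#' @param max_leaves leaf cap for the pruned CART (complexity raised until
#'   at most this many subgroups remain).
#' @param minN_ladder minimum-leaf-size ladder for the best-tree summaries.
#' @param m number of imputations (1 = single analysis; >= 2 adds Rubin
#'   pooling).
#' @param B_boot bootstrap replicates for the logistic baseline.
#' @param seed single global seed; all stage seeds are derived from it.
#' @param output_dir directory for the result bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = simulation_config(),
                            subgroup_vars = NULL,
                            forest = forest_config(),
                            cp = 0.2,
                            max_leaves = 10,
                            minN_ladder = c(1, 50, 100, 200),
                            m = 1,
                            B_boot = 500,
                            seed = 1L,
                            output_dir = "hteforest_results") {
  stopifnot(is_scalar_number(seed), m >= 1, cp >= 0, B_boot >= 100)
  structure(list(input = input, subgroup_vars = subgroup_vars,
                 forest = forest, cp = cp, max_leaves = max_leaves,
                 minN_ladder = minN_ladder, m = as.integer(m),
                 B_boot = as.integer(B_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

default_subgroup_vars <- function(trial) {
  prespecified <- c("age", "chronic_hypertension", "chronic_heart_failure",
                    "atherosclerotic_disease", "icnarc_risk", "sepsis3",
                    "vasopressor_type")
  additional <- c("male", "ethnicity", "prior_dependency",
                  "map_randomization", "admission_source", "apache_ii",
                  "icnarc_physiology", "cpr_24h", "sofa")
  intersect(c(prespecified, additional), baseline_covariates(trial))
}

# factor frame of subgroup variables: quintiles for continuous, yes/no for
# binary, factors passed through
build_subgroup_frame <- function(trial, vars) {
  missing_vars <- setdiff(vars, names(trial))
  if (length(missing_vars) > 0) {
    stopf("subgroup variable(s) not in the data: %s",
          paste(missing_vars, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(trial)))
  for (v in vars) {
    x <- trial[[v]]
    out[[v]] <- if (is.factor(x) || is.character(x)) {
      factor(x)
    } else if (all(x[!is.na(x)] %in% c(0, 1))) {
      factor(ifelse(x == 1, "yes", "no"), levels = c("no", "yes"))
    } else {
      quintile_groups(x)
    }
  }
  out
}

#' Merge method tables into the forest-plot table
#'
#' One row per (method, subgroup variable, level) with n, estimate, SE and
#' CI; duplicate keys are an error.
#'
#' @param ... `group_ate_result` data frames (from [group_ate_table()] and
#'   [logistic_gate_table()]).
#' @return A data frame with columns `method`, `subgroup_variable`, `level`,
#'   `n`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
forest_plot_table <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  tab <- do.call(rbind, lapply(tabs, function(t) {
    data.frame(method = t$method, subgroup_variable = t$subgroup_variable,
               level = t$level_label, n = t$n, estimate = t$estimate,
               se = t$se, ci_low = t$ci_low, ci_high = t$ci_high)
  }))
  key <- paste(tab$method, tab$subgroup_variable, tab$level, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate forest-plot rows: %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  }
  rownames(tab) <- NULL
  tab
}

analyze_one_dataset <- function(trial, cfg, subgroups) {
  model <- fit_causal_forest(trial, cfg$forest)
  cate <- predict(model)
  scores <- aipw_scores(model, trial)
  list(model = model,
       cate = cate,
       scores = scores,
       omnibus = omnibus_test(scores),
       cf_table = group_ate_table(scores, subgroups),
       logit_table = logistic_gate_table(trial, subgroups,
                                         B_boot = cfg$B_boot,
                                         seed = stage_seed(cfg$seed, "bootstrap")))
}

pool_gate_tables <- function(tables) {
  base <- tables[[1]]
  m <- length(tables)
  if (m == 1) return(base)
  for (r in seq_len(nrow(base))) {
    est <- vapply(tables, function(t) t$estimate[r], 0.0)
    v <- vapply(tables, function(t) t$se[r]^2, 0.0)
    rc <- rubin_combine(est, v)
    base$estimate[r] <- rc$estimate
    base$se[r] <- rc$se
    base$ci_low[r] <- rc$ci_low
    base$ci_high[r] <- rc$ci_high
  }
  base
}

pool_cates <- function(cates) {
  m <- length(cates)
  if (m == 1) return(cates[[1]])
  base <- cates[[1]]
  for (i in seq_len(nrow(base))) {
    est <- vapply(cates, function(c) c$tau_hat[i], 0.0)
    v <- vapply(cates, function(c) c$se[i]^2, 0.0)
    rc <- rubin_combine(est, v)
    base$tau_hat[i] <- rc$estimate
    base$se[i] <- rc$se
    base$ci_low[i] <- rc$ci_low
    base$ci_high[i] <- rc$ci_high
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates: trial input (or synthetic generation), chained-equation
#' imputation when covariates are missing, the two-pass honest causal
#' forest, out-of-bag CATE prediction, AIPW overall and subgroup ATEs, the
#' omnibus calibration/heterogeneity test, the logistic recycled-prediction
#' baseline with bootstrap CIs, Rubin pooling across imputations (when
#' `m >= 2`), and the post-hoc CATE exploration (second-stage OLS, pruned
#' CART with honest re-estimation on a held-out half, best-tree ladder, and
#' the in/out-of-sample R-squared comparison). Writes a machine-readable
#' result bundle; rerunning with the same configuration reproduces every
#' output byte-for-byte.
#'
#' Output files: `forest_plot.csv`, `individual_cates.csv`,
#' `cate_summary.json`, `omnibus.json`, `subgroup_tree.json` / `.txt`
#' (full-sample CART), `subgroup_tree_honest.json` / `.txt` and
#' `tree_leaves.csv` (honest split), `r2_comparison.csv`, `run_log.json`,
#' and `rubin_combined.csv` when `m >= 2`.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and `paths` to the
#'   files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(cfg$output_dir, f)
  stage <- "input"
  result <- tryCatch({
    trial <- if (inherits(cfg$input, "simulation_config")) {
      generate_trial(cfg$input)
    } else {
      read_trial(cfg$input)
    }
    subgroup_vars <- cfg$subgroup_vars %||% default_subgroup_vars(trial)
    covs <- baseline_covariates(trial)

    stage <- "imputation"
    has_missing <- anyNA(trial[, covs])
    imp <- if (has_missing || cfg$m > 1) {
      mice_impute(trial, m = cfg$m, seed = stage_seed(cfg$seed, "impute"))
    } else {
      structure(list(completed = list(trial), m = 1L, iterations = 0L,
                     seed = cfg$seed,
                     methods = setNames(rep("none", length(covs)), covs)),
                class = "imputation_set")
    }

    stage <- "forest"
    analyses <- lapply(imp$completed, function(tr) {
      analyze_one_dataset(tr, cfg, build_subgroup_frame(tr, subgroup_vars))
    })

    stage <- "aggregation"
    cf_table <- pool_gate_tables(lapply(analyses, `[[`, "cf_table"))
    logit_table <- pool_gate_tables(lapply(analyses, `[[`, "logit_table"))
    fp_table <- forest_plot_table(logit_table, cf_table)
    cate <- pool_cates(lapply(analyses, `[[`, "cate"))
    omnibus <- analyses[[1]]$omnibus

    stage <- "cate_exploration"
    trial1 <- imp$completed[[1]]
    cov_df <- as.data.frame(trial1)[, covs, drop = FALSE]
    cart_full <- fit_pruned_cart(cate, cov_df, cp = cfg$cp,
                                 max_leaves = cfg$max_leaves,
                                 training_ids = trial1$id)
    # honest split: discover subgroups on half A, re-estimate on half B
    n <- nrow(trial1)
    idx_a <- with_seed(stage_seed(cfg$seed, "explore-split"),
                       sort(sample.int(n, n %/% 2)))
    idx_b <- setdiff(seq_len(n), idx_a)
    cart_honest <- fit_pruned_cart(cate[idx_a, ], cov_df[idx_a, , drop = FALSE],
                                   cp = cfg$cp, max_leaves = cfg$max_leaves,
                                   training_ids = trial1$id[idx_a])
    scores1 <- analyses[[1]]$scores
    scores_b <- scores1[idx_b, , drop = FALSE]
    class(scores_b) <- class(scores1)
    attr(scores_b, "propensity") <- attr(scores1, "propensity")
    cart_honest <- honest_subgroup_ates(cart_honest, scores_b,
                                        cov_df[idx_b, , drop = FALSE])

    # one-hot encode for the linear model so rare factor levels absent from
    # the training half cannot break out-of-sample prediction
    cov_enc <- as.data.frame(encode_covariates(cov_df, covariates = covs))
    names(cov_enc) <- make.names(names(cov_enc))
    ols_fit <- suppressWarnings(
      second_stage_ols(cate[idx_a, ], cov_enc[idx_a, , drop = FALSE]))
    r2_rows <- list(data.frame(
      method = "ols", param = NA_real_, leaves = NA_integer_,
      r2_in_sample = r2_explained(
        predict(ols_fit, cov_enc[idx_a, , drop = FALSE]), cate[idx_a, ]),
      r2_out_of_sample = r2_explained(
        predict(ols_fit, cov_enc[idx_b, , drop = FALSE]), cate[idx_b, ])))
    r2_rows[[2]] <- data.frame(
      method = "cart", param = cfg$cp, leaves = cart_honest$leaf_count,
      r2_in_sample = r2_explained(
        predict(cart_honest, cov_df[idx_a, , drop = FALSE]), cate[idx_a, ]),
      r2_out_of_sample = r2_explained(
        predict(cart_honest, cov_df[idx_b, , drop = FALSE]), cate[idx_b, ]))
    for (minN in cfg$minN_ladder) {
      bt <- best_tree(cate[idx_a, ], cov_df[idx_a, , drop = FALSE],
                      minN = minN,
                      seed = stage_seed(cfg$seed, paste0("best-tree-", minN)),
                      training_ids = trial1$id[idx_a])
      r2_rows[[length(r2_rows) + 1]] <- data.frame(
        method = "best_tree", param = minN, leaves = bt$leaf_count,
        r2_in_sample = r2_explained(
          predict(bt, cov_df[idx_a, , drop = FALSE]), cate[idx_a, ]),
        r2_out_of_sample = r2_explained(
          predict(bt, cov_df[idx_b, , drop = FALSE]), cate[idx_b, ]))
    }
    r2_table <- do.call(rbind, r2_rows)

    stage <- "report"
    paths <- list()
    write.csv(fp_table, paths$forest_plot <- out_path("forest_plot.csv"),
              row.names = FALSE)
    cate_sorted <- cate[order(cate$tau_hat), ]
    write.csv(cate_sorted,
              paths$individual_cates <- out_path("individual_cates.csv"),
              row.names = FALSE)
    summary_json <- list(
      n = nrow(cate),
      cate_min = min(cate$tau_hat), cate_max = max(cate$tau_hat),
      share_negative = mean(cate$tau_hat < 0),
      share_ci_excludes_zero = mean(cate$ci_high < 0 | cate$ci_low > 0),
      share_negative_ci_below_zero = mean(cate$ci_high < 0),
      share_ci_includes_zero = mean(cate$ci_low <= 0 & cate$ci_high >= 0))
    jsonlite::write_json(summary_json,
                         paths$cate_summary <- out_path("cate_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_omnibus_json(omnibus, paths$omnibus <- out_path("omnibus.json"))
    write_subgroup_tree(cart_full,
                        paths$subgroup_tree <- out_path("subgroup_tree.json"))
    writeLines(render_tree_text(cart_full), out_path("subgroup_tree.txt"))
    write_subgroup_tree(cart_honest,
                        paths$subgroup_tree_honest <-
                          out_path("subgroup_tree_honest.json"),
                        csv_path = paths$tree_leaves <-
                          out_path("tree_leaves.csv"))
    writeLines(render_tree_text(cart_honest),
               out_path("subgroup_tree_honest.txt"))
    write.csv(r2_table, paths$r2_comparison <- out_path("r2_comparison.csv"),
              row.names = FALSE)
    if (imp$m >= 2) {
      write.csv(cf_table, paths$rubin_combined <-
                  out_path("rubin_combined.csv"), row.names = FALSE)
    }
    model1 <- analyses[[1]]$model
    log_json <- list(
      seed = cfg$seed,
      stage_seeds = list(impute = stage_seed(cfg$seed, "impute"),
                         bootstrap = stage_seed(cfg$seed, "bootstrap"),
                         explore_split = stage_seed(cfg$seed, "explore-split")),
      m = imp$m,
      n = nrow(trial),
      num_trees = model1$forest$num_trees,
      two_pass = model1$two_pass,
      importance_multiplier = cfg$forest$importance_multiplier,
      selected_covariates = model1$selected,
      pass1_importance = as.list(model1$pass1_importance),
      clip_count = attr(trial, "clip_count"),
      subgroup_vars = subgroup_vars,
      package_version = as.character(utils::packageVersion("hteforest")))
    jsonlite::write_json(log_json, paths$run_log <- out_path("run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")

    invisible(list(trial = trial, imputations = imp, analyses = analyses,
                   forest_plot = fp_table, cate = cate, omnibus = omnibus,
                   cart_full = cart_full, cart_honest = cart_honest,
                   r2_table = r2_table, paths = paths))
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  result
}
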
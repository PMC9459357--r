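#' Default baseline covariate specification
#'
#' Covariate descriptors emulating the marginal distributions of the baseline
#' table of a large pragmatic critical-care trial of permissive hypotension in
#' patients aged 65 years or over with vasodilatory hypotension: age (truncated
#' normal, lower bound 65), sex, comorbidities (chronic hypertension ~45.8%,
#' atherosclerotic disease, chronic heart failure), prior dependency, admission
#' source, severity scores (APACHE II, ICNARC physiology, SOFA), mean arterial
#' pressure at randomization, vasopressor duration and type, Sepsis-3 category
#' (septic shock ~48.3%), ethnicity, prior CPR, and a predicted risk of death.
#'
#' Marginals are independent by default; severity scores can be correlated via
#' the `score_correlation` knob (a Gaussian copula across the continuous
#' scores). The predicted risk of death is not the proprietary prognostic
#' model: it is simulated as a logistic function of the severity scores and
#' age plus noise, calibrated to a median near 0.33 and IQR near (0.15, 0.60).
#'
#' @param score_correlation correlation in (0, 1) shared by the continuous
#'   severity scores (age, APACHE II, ICNARC physiology, SOFA); 0 (default)
#'   keeps all marginals independent.
#' @return A list of covariate descriptors, each with elements `name`,
#'   `kind` (`"continuous"`, `"binary"`, `"categorical"` or `"derived"`) and
#'   kind-specific parameters.
#' @export
default_covariate_spec <- function(score_correlation = 0) {
  stopifnot(is_scalar_number(score_correlation),
            score_correlation >= 0, score_correlation < 1)
  spec <- list(
    list(name = "age", kind = "continuous", dist = "truncnorm",
         mean = 75.2, sd = 6.8, lower = 65),
    list(name = "male", kind = "binary", p = 0.566),
    list(name = "chronic_hypertension", kind = "binary", p = 0.458),
    list(name = "atherosclerotic_disease", kind = "binary", p = 0.145),
    list(name = "chronic_heart_failure", kind = "binary", p = 0.110),
    list(name = "prior_dependency", kind = "binary", p = 0.324),
    list(name = "admission_source", kind = "categorical",
         levels = c("ed_or_community", "elective_surgery", "emergency_surgery",
                    "other_critical_care", "ward"),
         probs = c(0.347, 0.046, 0.212, 0.015, 0.380)),
    list(name = "apache_ii", kind = "continuous", dist = "normal",
         mean = 20.75, sd = 6.3),
    list(name = "icnarc_physiology", kind = "continuous", dist = "normal",
         mean = 23.7, sd = 8.8),
    list(name = "sofa", kind = "continuous", dist = "truncnorm",
         mean = 5.5, sd = 1.95, lower = 0),
    list(name = "map_randomization", kind = "continuous", dist = "normal",
         mean = 70.4, sd = 10.9),
    list(name = "vasopressor_duration", kind = "continuous",
         dist = "lognormal", meanlog = log(186), sdlog = 0.74),
    list(name = "sepsis3", kind = "categorical",
         levels = c("no_sepsis", "sepsis_no_shock", "septic_shock"),
         probs = c(0.219, 0.298, 0.483)),
    list(name = "vasopressor_type", kind = "categorical",
         levels = c("none", "norepinephrine_low", "norepinephrine_high",
                    "metaraminol", "other_combination"),
         probs = c(0.015, 0.117, 0.530, 0.313, 0.011)),
    list(name = "ethnicity", kind = "categorical",
         levels = c("white", "black_black_mixed", "asian_asian_mixed",
                    "other_not_stated"),
         probs = c(0.938, 0.011, 0.015, 0.037)),
    list(name = "cpr_24h", kind = "categorical",
         levels = c("community_cpr", "in_hospital_cpr", "no_cpr"),
         probs = c(0.019, 0.030, 0.951)),
    list(name = "icnarc_risk", kind = "derived",
         fn = function(data) {
           lp <- -3.55 + 0.12 * (data$icnarc_physiology - 23.7) +
             0.05 * (data$apache_ii - 20.75) + 0.02 * (data$age - 75.2) +
             0.12 * 23.7 + rnorm(nrow(data), 0, 1.1)
           plogis(lp)
         })
  )
  if (score_correlation > 0) {
    attr(spec, "score_correlation") <- score_correlation
    attr(spec, "correlated_scores") <-
      c("age", "apache_ii", "icnarc_physiology", "sofa")
  }
  spec
}

#' Step CATE in chronic hypertension
#'
#' Treatment-effect function (risk-difference scale, negative = mortality
#' benefit) taking one value for patients with chronic hypertension and
#' another for everyone else. This is the package's default simulation truth:
#' a modest mortality benefit concentrated in the hypertensive subgroup.
#'
#' @param tau_hypertensive effect for patients with chronic hypertension.
#' @param tau_other effect for all other patients.
#' @return A function mapping a trial covariate data frame to a numeric
#'   vector of true treatment effects.
#' @export
cate_step_hypertension <- function(tau_hypertensive = -0.06,
                                   tau_other = -0.02) {
  force(tau_hypertensive); force(tau_other)
  function(data) {
    ifelse(data$chronic_hypertension == 1, tau_hypertensive, tau_other)
  }
}

#' Null (homogeneous) CATE
#'
#' @param tau the constant treatment effect (default 0).
#' @return A function mapping covariates to a constant effect.
#' @export
cate_constant <- function(tau = 0) {
  force(tau)
  function(data) rep(tau, nrow(data))
}

#' Default control-arm mortality risk
#'
#' Logistic function of the severity scores, age and septic shock, centred so
#' that overall control-arm 90-day mortality is roughly 35%, in line with a
#' critically ill population aged 65 and over with vasodilatory hypotension.
#'
#' @return A function mapping a covariate data frame to control-arm event
#'   probabilities.
#' @export
default_baseline_risk <- function() {
  function(data) {
    lp <- qlogis(0.35) +
      0.55 * (data$icnarc_physiology - 23.7) / 8.8 +
      0.30 * (data$apache_ii - 20.75) / 6.3 +
      0.25 * (data$age - 75.2) / 6.8 +
      0.30 * (data$sepsis3 == "septic_shock") +
      0.15 * (data$sofa - 5.5) / 1.95
    plogis(lp)
  }
}

#' Simulation configuration for a synthetic two-arm trial
#'
#' @param n number of patients (>= 20).
#' @param covariate_spec list of covariate descriptors; see
#'   [default_covariate_spec()].
#' @param baseline_risk function of the covariate data frame giving the
#'   control-arm event probability for each patient.
#' @param cate_fn function of the covariate data frame giving the true
#'   treatment effect tau(x) on the risk-difference scale (negative values
#'   mean the treatment reduces mortality).
#' @param propensity randomization probability of treatment, in (0, 1).
#' @param seed integer seed; the whole table is a deterministic function of
#'   the configuration including the seed.
#' @param missing_rate probability in `[0, 1]` that each covariate cell is
#'   independently set missing (MCAR); treatment, outcome and truth columns
#'   are never masked.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n = 2463,
                              covariate_spec = default_covariate_spec(),
                              baseline_risk = default_baseline_risk(),
                              cate_fn = cate_step_hypertension(),
                              propensity = 0.5,
                              seed = 1L,
                              missing_rate = 0) {
  stopifnot(is_scalar_number(n), n >= 20,
            is_scalar_number(propensity), propensity > 0, propensity < 1,
            is.function(baseline_risk), is.function(cate_fn),
            is_scalar_number(missing_rate), missing_rate >= 0,
            missing_rate <= 1, is_scalar_number(seed))
  validate_covariate_spec(covariate_spec)
  structure(list(n = as.integer(n), covariate_spec = covariate_spec,
                 baseline_risk = baseline_risk, cate_fn = cate_fn,
                 propensity = propensity, seed = as.integer(seed),
                 missing_rate = missing_rate),
            class = "simulation_config")
}

validate_covariate_spec <- function(spec) {
  if (!is.list(spec) || length(spec) == 0) {
    stopf("covariate_spec must be a nonempty list of descriptors")
  }
  for (cv in spec) {
    nm <- cv$name %||% "<unnamed>"
    bad <- function(msg) {
      stopf("invalid covariate specification for '%s': %s", nm, msg)
    }
    if (is.null(cv$name) || !nzchar(cv$name)) bad("missing name")
    kind <- cv$kind %||% bad("missing kind")
    if (kind == "binary") {
      if (!is_scalar_number(cv$p) || cv$p < 0 || cv$p > 1) {
        bad("binary probability p must lie in [0, 1]")
      }
    } else if (kind == "categorical") {
      if (length(cv$levels) < 2) bad("needs >= 2 levels")
      if (length(cv$probs) != length(cv$levels) || any(cv$probs < 0) ||
          abs(sum(cv$probs) - 1) > 0.02) {
        bad("probs must be nonnegative, match levels and sum to ~1")
      }
    } else if (kind == "continuous") {
      dist <- cv$dist %||% "normal"
      if (dist %in% c("normal", "truncnorm")) {
        if (!is_scalar_number(cv$mean) || !is_scalar_number(cv$sd) ||
            cv$sd <= 0) {
          bad("normal parameters mean/sd invalid")
        }
      } else if (dist == "lognormal") {
        if (!is_scalar_number(cv$meanlog) || !is_scalar_number(cv$sdlog) ||
            cv$sdlog <= 0) {
          bad("lognormal parameters meanlog/sdlog invalid")
        }
      } else {
        bad(sprintf("unknown continuous distribution '%s'", dist))
      }
    } else if (kind == "derived") {
      if (!is.function(cv$fn)) bad("derived covariate needs fn")
    } else {
      bad(sprintf("unknown kind '%s'", kind))
    }
  }
  invisible(TRUE)
}

draw_covariates <- function(spec, n) {
  data <- data.frame(row.names = seq_len(n))
  rho <- attr(spec, "score_correlation")
  corr_names <- attr(spec, "correlated_scores")
  z_shared <- if (!is.null(rho)) rnorm(n) else NULL
  for (cv in spec) {
    x <- switch(cv$kind,
      binary = rbinom(n, 1L, cv$p),
      categorical = factor(
        sample(cv$levels, n, replace = TRUE, prob = cv$probs / sum(cv$probs)),
        levels = cv$levels),
      continuous = {
        dist <- cv$dist %||% "normal"
        z <- rnorm(n)
        if (!is.null(rho) && cv$name %in% corr_names) {
          z <- sqrt(rho) * z_shared + sqrt(1 - rho) * z
        }
        if (dist == "normal") {
          cv$mean + cv$sd * z
        } else if (dist == "truncnorm") {
          # inverse-CDF draw from the parent normal truncated below at `lower`
          plo <- pnorm(cv$lower, cv$mean, cv$sd)
          u <- plo + (1 - plo) * pnorm(z)
          qnorm(u, cv$mean, cv$sd)
        } else {
          exp(cv$meanlog + cv$sdlog * z)
        }
      },
      derived = {
        v <- cv$fn(data)
        if (length(v) != n) {
          stopf("derived covariate '%s' returned %d values for %d rows",
                cv$name, length(v), n)
        }
        v
      })
    data[[cv$name]] <- x
  }
  data
}

#' Generate a synthetic two-arm randomized trial with known truth
#'
#' Draws baseline covariates from the configuration's marginal descriptors,
#' evaluates the control-arm risk and the true treatment-effect function
#' tau(x), clips the implied potential-outcome risks to `[0.001, 0.999]`
#' (clipping events are counted and recorded in the `clip_count` attribute),
#' draws both potential outcomes and a Bernoulli treatment assignment, and
#' returns the observed table together with the stored truth columns
#' (`true_tau`, `y0`, `y1`). The observed outcome satisfies
#' `Y = D * y1 + (1 - D) * y0` by construction.
#'
#' @param config a [simulation_config()].
#' @return A `trial_table`: a data frame with columns `id`, the covariates,
#'   `treatment`, `outcome`, `true_tau`, `y0`, `y1`; attributes record the
#'   configuration, design propensity, covariate names and clip count.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  trial <- with_seed(config$seed, {
    data <- draw_covariates(config$covariate_spec, n)
    p0 <- config$baseline_risk(data)
    if (length(p0) != n || any(!is.finite(p0))) {
      stopf("baseline_risk must return %d finite probabilities", n)
    }
    tau <- config$cate_fn(data)
    if (length(tau) != n || any(!is.finite(tau))) {
      stopf("cate_fn must return %d finite values", n)
    }
    p1 <- p0 + tau
    clip <- function(p) pmin(pmax(p, 0.001), 0.999)
    clip_count <- sum(p0 < 0.001 | p0 > 0.999) + sum(p1 < 0.001 | p1 > 0.999)
    p0c <- clip(p0); p1c <- clip(p1)
    treatment <- rbinom(n, 1L, config$propensity)
    y0 <- rbinom(n, 1L, p0c)
    y1 <- rbinom(n, 1L, p1c)
    out <- cbind(data.frame(id = seq_len(n)), data)
    out$treatment <- treatment
    out$outcome <- treatment * y1 + (1L - treatment) * y0
    out$true_tau <- p1c - p0c
    out$y0 <- y0
    out$y1 <- y1
    attr(out, "clip_count") <- clip_count
    out
  })
  clip_count <- attr(trial, "clip_count")
  if (clip_count > 0) {
    warnf("%d potential-outcome risks clipped to [0.001, 0.999]", clip_count)
  }
  trial <- as_trial_table(trial,
                          covariates = vapply(config$covariate_spec,
                                              `[[`, "", "name"),
                          propensity = config$propensity)
  attr(trial, "config") <- config
  attr(trial, "clip_count") <- clip_count
  if (config$missing_rate > 0) {
    trial <- inject_missingness(trial, config$missing_rate,
                                seed = stage_seed(config$seed, "missingness"))
  }
  trial
}

#' Mark a data frame as a trial table
#'
#' @param data data frame with one row per patient containing a binary
#'   `treatment` column, a binary `outcome` column and baseline covariates.
#' @param covariates character vector naming the baseline covariate columns;
#'   defaults to everything except `id`, `treatment`, `outcome` and the truth
#'   columns.
#' @param propensity the design randomization probability.
#' @return The data frame with class `trial_table` and attributes set.
#' @export
as_trial_table <- function(data, covariates = NULL, propensity = 0.5) {
  stopifnot(is.data.frame(data),
            all(c("treatment", "outcome") %in% names(data)))
  if (anyNA(data$treatment) || anyNA(data$outcome)) {
    stopf("treatment and outcome must not contain missing values")
  }
  if (!all(data$treatment %in% c(0, 1))) stopf("treatment must be binary 0/1")
  if (!all(data$outcome %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (is.null(data$id)) data$id <- seq_len(nrow(data))
  covariates <- covariates %||%
    setdiff(names(data), c("id", "treatment", "outcome", "true_tau", "y0", "y1"))
  class(data) <- c("trial_table", "data.frame")
  attr(data, "covariates") <- covariates
  attr(data, "propensity") <- propensity
  data
}

#' Baseline covariate column names of a trial table
#' @param trial a `trial_table`.
#' @return Character vector of covariate column names.
#' @export
baseline_covariates <- function(trial) {
  attr(trial, "covariates") %||%
    setdiff(names(trial), c("id", "treatment", "outcome", "true_tau", "y0", "y1"))
}

#' True subgroup average treatment effect (synthetic data only)
#'
#' Oracle used to validate estimators: the mean of the stored true
#' treatment-effect column over a subgroup.
#'
#' @param trial a synthetic `trial_table` carrying a `true_tau` column.
#' @param group logical vector selecting a nonempty subgroup.
#' @return The true group average treatment effect (risk difference).
#' @export
true_group_ate <- function(trial, group) {
  if (is.null(trial$true_tau)) {
    stopf("trial has no true_tau column; true_group_ate needs synthetic data")
  }
  stopifnot(is.logical(group), length(group) == nrow(trial))
  if (!any(group)) stopf("group is empty")
  mean(trial$true_tau[group])
}

#' Inject MCAR missingness into baseline covariates
#'
#' Each covariate cell is independently set missing with probability `rate`.
#' Treatment, outcome and the synthetic truth columns are never altered.
#'
#' @param trial a `trial_table`.
#' @param rate missingness probability in `[0, 1]`.
#' @param seed integer seed.
#' @return The trial table with missing covariate cells.
#' @export
inject_missingness <- function(trial, rate, seed = 1L) {
  if (!is_scalar_number(rate) || rate < 0 || rate > 1) {
    stopf("missingness rate must lie in [0, 1]")
  }
  if (rate == 0) return(trial)
  covs <- baseline_covariates(trial)
  with_seed(seed, {
    for (cv in covs) {
      mask <- runif(nrow(trial)) < rate
      trial[[cv]][mask] <- NA
    }
  })
  trial
}

#' Quintile subgroups of a continuous covariate
#'
#' Groups formed from sample quintiles; values tied with a quintile boundary
#' are assigned to the lower quintile.
#'
#' @param x numeric vector.
#' @return Factor with levels `Q1`..`Q5` (fewer when quantiles tie).
#' @export
quintile_groups <- function(x) {
  breaks <- unique(quantile(x, probs = seq(0, 1, 0.2), na.rm = TRUE,
                            names = FALSE))
  labs <- paste0("Q", seq_len(length(breaks) - 1))
  cut(x, breaks = breaks, labels = labs, include.lowest = TRUE, right = TRUE)
}

#' Write / read a trial table as CSV with a JSON sidecar
#'
#' The CSV stores missing values as empty fields. The sidecar (`<path>.json`)
#' records column types, factor levels, covariate names, the design
#' propensity and, for synthetic tables, the simulation seed and clip count,
#' so a written table round-trips exactly.
#'
#' @param trial a `trial_table`.
#' @param path CSV path.
#' @return `write_trial` invisibly returns `path`; `read_trial` returns the
#'   restored `trial_table`.
#' @export
write_trial <- function(trial, path) {
  config <- attr(trial, "config")
  covs <- baseline_covariates(trial)
  sidecar <- list(
    covariates = covs,
    propensity = attr(trial, "propensity") %||% 0.5,
    column_classes = lapply(trial, function(col) class(col)[1]),
    factor_levels = lapply(Filter(is.factor, trial[covs]), levels),
    clip_count = attr(trial, "clip_count"),
    seed = if (!is.null(config)) config$seed,
    n = nrow(trial),
    missing_rate = if (!is.null(config)) config$missing_rate
  )
  df <- as.data.frame(trial)
  write.csv(df, path, row.names = FALSE, na = "")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (!is.null(sidecar$factor_levels)) {
    for (nm in names(sidecar$factor_levels)) {
      df[[nm]] <- factor(df[[nm]], levels = sidecar$factor_levels[[nm]])
    }
  } else {
    for (nm in names(df)) {
      if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    }
  }
  as_trial_table(df,
                 covariates = sidecar$covariates %||% NULL,
                 propensity = sidecar$propensity %||% 0.5)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Two-arm trial table: %d patients (%d treated, %d control)\n",
              nrow(x), sum(x$treatment == 1), sum(x$treatment == 0)))
  cat(sprintf("Outcome events: %d (%.1f%%); covariates: %d%s\n",
              sum(x$outcome), 100 * mean(x$outcome),
              length(baseline_covariates(x)),
              if (!is.null(x$true_tau)) "; synthetic truth stored" else ""))
  invisible(x)
}
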
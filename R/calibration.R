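#' Omnibus calibration and heterogeneity test
#'
#' Best-linear-predictor construction: the doubly robust scores
#' \eqn{\Gamma_i} are regressed (no intercept) on two synthetic regressors,
#' the mean out-of-bag forest prediction \eqn{\bar\tau} (a constant) and the
#' demeaned out-of-bag prediction \eqn{\hat\tau_i - \bar\tau}. A coefficient
#' of 1 on the first regressor means the mean forest prediction is correct
#' (calibrated ATE); a coefficient of 1 on the second means the forest's
#' heterogeneity estimates are well calibrated, and a positive coefficient is
#' evidence of true heterogeneity. Standard errors are
#' heteroskedasticity-robust (HC3). The ATE p-value is the two-sided test of
#' coefficient = 1; the heterogeneity p-value is the one-sided test of
#' coefficient > 0, which doubles as a test of the null of homogeneous
#' effects.
#'
#' When the out-of-bag predictions have (numerically) zero variance the
#' heterogeneity coefficient is not estimable; it is returned as `NA` with a
#' one-sided p-value of 1 and a note.
#'
#' @param scores an `aipw_scores` data frame.
#' @param oob_cate optional `cate_estimate` (or numeric vector) of out-of-bag
#'   predictions; defaults to the `tau_oob` column of `scores`.
#' @return A list of class `omnibus_result` with elements `ate_coefficient`,
#'   `ate_se`, `ate_p`, `het_coefficient`, `het_se`, `het_p_one_sided`,
#'   `het_estimable`, `n`.
#' @export
omnibus_test <- function(scores, oob_cate = NULL) {
  stopifnot(inherits(scores, "aipw_scores"))
  tau <- if (is.null(oob_cate)) {
    scores$tau_oob
  } else if (is.numeric(oob_cate)) {
    oob_cate
  } else {
    oob_cate$tau_hat
  }
  gamma <- scores$gamma
  n <- length(gamma)
  stopifnot(length(tau) == n)
  tbar <- mean(tau)
  mean_reg <- rep(tbar, n)
  diff_reg <- tau - tbar

  eps <- .Machine$double.eps^0.75
  het_estimable <- var(diff_reg) > eps
  ate_estimable <- abs(tbar) > eps

  if (!het_estimable && !ate_estimable) {
    # degenerate: predictions identically zero, no usable regressor
    res <- list(ate_coefficient = NA_real_, ate_se = NA_real_, ate_p = NA_real_,
                het_coefficient = NA_real_, het_se = NA_real_,
                het_p_one_sided = 1, het_estimable = FALSE, n = n,
                note = "forest predictions are identically zero")
    class(res) <- "omnibus_result"
    return(res)
  }

  if (het_estimable && !ate_estimable) {
    # mean prediction exactly zero: only the heterogeneity regressor is usable
    fit <- lm(gamma ~ 0 + diff_reg)
    V <- sandwich::vcovHC(fit, type = "HC3")
    b <- coef(fit)[[1]]
    se <- sqrt(V[1, 1])
    df <- n - 1
    res <- list(ate_coefficient = NA_real_, ate_se = NA_real_, ate_p = NA_real_,
                het_coefficient = b, het_se = se,
                het_p_one_sided = pt(b / se, df, lower.tail = FALSE),
                het_estimable = TRUE, n = n,
                note = "mean forest prediction is zero; ATE coefficient not estimable")
    class(res) <- "omnibus_result"
    return(res)
  }

  if (het_estimable) {
    fit <- lm(gamma ~ 0 + mean_reg + diff_reg)
    V <- sandwich::vcovHC(fit, type = "HC3")
    b <- coef(fit)
    se <- sqrt(diag(V))
    df <- n - 2
    ate_t <- (b[["mean_reg"]] - 1) / se[["mean_reg"]]
    het_t <- b[["diff_reg"]] / se[["diff_reg"]]
    res <- list(ate_coefficient = unname(b[["mean_reg"]]),
                ate_se = unname(se[["mean_reg"]]),
                ate_p = 2 * pt(abs(ate_t), df, lower.tail = FALSE),
                het_coefficient = unname(b[["diff_reg"]]),
                het_se = unname(se[["diff_reg"]]),
                het_p_one_sided = pt(het_t, df, lower.tail = FALSE),
                het_estimable = TRUE, n = n)
  } else {
    fit <- lm(gamma ~ 0 + mean_reg)
    V <- sandwich::vcovHC(fit, type = "HC3")
    b <- coef(fit)[[1]]
    se <- sqrt(V[1, 1])
    df <- n - 1
    res <- list(ate_coefficient = b, ate_se = se,
                ate_p = 2 * pt(abs((b - 1) / se), df, lower.tail = FALSE),
                het_coefficient = NA_real_, het_se = NA_real_,
                het_p_one_sided = 1, het_estimable = FALSE, n = n,
                note = "constant forest predictions; heterogeneity not estimable")
  }
  class(res) <- "omnibus_result"
  res
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat("Omnibus calibration / heterogeneity test\n")
  cat(sprintf("  mean prediction (ATE) coefficient: %.3f (SE %.3f), two-sided P vs 1 = %.3f\n",
              x$ate_coefficient, x$ate_se, x$ate_p))
  if (x$het_estimable) {
    cat(sprintf("  heterogeneity coefficient: %.3f (SE %.3f), one-sided P = %.3f\n",
                x$het_coefficient, x$het_se, x$het_p_one_sided))
  } else {
    cat("  heterogeneity coefficient: not estimable (constant predictions)\n")
  }
  cat(sprintf("  n = %d\n", x$n))
  invisible(x)
}

#' Serialize an omnibus result to JSON
#' @param result an `omnibus_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_omnibus_json <- function(result, path) {
  jsonlite::write_json(
    list(ate_coefficient = result$ate_coefficient, ate_se = result$ate_se,
         ate_p = result$ate_p, het_coefficient = result$het_coefficient,
         het_se = result$het_se, het_p = result$het_p_one_sided,
         het_estimable = result$het_estimable, n = result$n),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
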
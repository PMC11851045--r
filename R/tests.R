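new_test_result <- function(name, statistic, df, p, alpha = 0.1,
                            note = NULL) {
  structure(list(name = name, statistic = statistic, df = df, p = p,
                 alpha = alpha,
                 decision = if (p < alpha) "reject H0" else "keep H0",
                 note = note),
            class = "spatial_test")
}

#' @export
print.spatial_test <- function(x, ...) {
  cat(sprintf("%-28s stat = %8.3f  df = %s  p = %.4g  -> %s\n",
              x$name, x$statistic, format(x$df), x$p, x$decision))
  if (!is.null(x$note)) cat("   note:", x$note, "\n")
  invisible(x)
}

tests_as_df <- function(tests) {
  do.call(rbind, lapply(tests, function(t) {
    data.frame(test = t$name, statistic = t$statistic, df = t$df, p = t$p,
               decision = t$decision, stringsAsFactors = FALSE)
  }))
}

#' Lagrange multiplier tests for spatial dependence
#'
#' Score tests on the residuals of a non-spatial within regression,
#' pointing at a spatially lagged outcome (LM-lag), a spatially
#' autocorrelated error (LM-error), and their robust variants that guard
#' each against local presence of the other. Pooled-panel forms on the
#' demeaned data: with `e` the stacked OLS residuals, `sigma2 = e'e/NT`,
#' `T_W = tr(W'W + WW)`,
#' `LM_err = [e'(I_T (x) W)e / sigma2]^2 / (T * T_W)` and
#' `LM_lag = [e'(I_T (x) W)y / sigma2]^2 / J` with
#' `J = [(WXb)'M(WXb) + T*T_W*sigma2] / sigma2`. All four statistics refer
#' to a chi-square(1) reference.
#'
#' @param ols A `panel_fit` from [fit_panel_ols()].
#' @param w Row-standardized `spatial_weights`.
#' @param alpha Decision level recorded on each test (default 0.1).
#' @return Named list of four `spatial_test` objects: `lm_lag`, `lm_error`,
#'   `rlm_lag`, `rlm_error`.
#' @export
lm_spatial_tests <- function(ols, w, alpha = 0.1) {
  stopifnot(inherits(ols, "panel_fit"), ols$model == "OLS",
            inherits(w, "spatial_weights"))
  if (!w$standardized) {
    warning("weights are not row-standardized; standardizing for LM tests")
    w <- row_standardize(w)
  }
  Wm <- w$W
  n <- ols$n; T_ <- ols$T; NT <- n * T_
  e <- ols$resid                       # n x T
  ydm <- ols$demeaned$y
  Z <- ols$demeaned$Z
  sigma2 <- sum(e^2) / NT
  if (sigma2 <= 0) stop("degenerate residual variance")
  TW <- sum(t(Wm) * Wm) + sum(Wm * Wm)     # tr(W'W + WW)
  T1 <- T_ * TW

  eWe <- sum(e * (Wm %*% e))
  eWy <- sum(e * (Wm %*% ydm))
  d_lam <- eWe / sigma2
  d_rho <- eWy / sigma2

  WXb <- as.vector(Wm %*% ols$fitted)      # W X beta-hat, stacked
  MWXb <- WXb - drop(Z %*% qr.coef(qr(Z), WXb))
  J <- (sum(WXb * MWXb) + T1 * sigma2) / sigma2

  p1 <- function(s) stats::pchisq(s, df = 1, lower.tail = FALSE)
  lm_lag <- d_rho^2 / J
  lm_err <- d_lam^2 / T1
  rlm_lag <- (d_rho - d_lam)^2 / (J - T1)
  rlm_err <- (d_lam - (T1 / J) * d_rho)^2 / (T1 * (1 - T1 / J))
  list(
    lm_lag = new_test_result("LM-lag", lm_lag, 1L, p1(lm_lag), alpha),
    lm_error = new_test_result("LM-error", lm_err, 1L, p1(lm_err), alpha),
    rlm_lag = new_test_result("robust LM-lag", rlm_lag, 1L, p1(rlm_lag),
                              alpha),
    rlm_error = new_test_result("robust LM-error", rlm_err, 1L,
                                p1(rlm_err), alpha)
  )
}

#' Wald tests for reducing an SDM to SAR or SEM
#'
#' SDM -> SAR tests `H0: theta = 0` (no spatially lagged covariates);
#' SDM -> SEM tests the common-factor restriction
#' `H0: theta + rho * beta = 0`, whose covariance is obtained by the delta
#' method over (beta, theta, rho). Both statistics refer to chi-square(k).
#'
#' @param sdm A converged SDM `panel_fit`.
#' @param alpha Decision level (default 0.1).
#' @return Named list of `spatial_test`s: `wald_sar`, `wald_sem`.
#' @export
wald_reduction_tests <- function(sdm, alpha = 0.1) {
  stopifnot(inherits(sdm, "panel_fit"), sdm$model == "SDM")
  k <- length(sdm$beta)
  bn <- names(sdm$beta)
  tn <- names(sdm$theta)
  V <- sdm$vcov

  quad <- function(g, Vg, name) {
    sol <- tryCatch(solve(Vg, g), error = function(e) NULL)
    note <- NULL
    if (is.null(sol)) {
      sol <- MASS::ginv(Vg) %*% g
      note <- "singular restriction covariance; pseudo-inverse used"
    }
    stat <- max(0, drop(crossprod(g, sol)))
    new_test_result(name, stat, k,
                    stats::pchisq(stat, df = k, lower.tail = FALSE),
                    alpha, note)
  }
  w_sar <- quad(sdm$theta, V[tn, tn, drop = FALSE], "Wald SDM->SAR")

  g <- sdm$theta + sdm$rho * sdm$beta
  A <- cbind(diag(sdm$rho, k), diag(k), matrix(sdm$beta, k, 1L))
  idx <- c(bn, tn, "rho")
  Vg <- A %*% V[idx, idx] %*% t(A)
  w_sem <- quad(g, Vg, "Wald SDM->SEM")
  list(wald_sar = w_sar, wald_sem = w_sem)
}

#' Likelihood-ratio test between nested panel fits
#'
#' `LR = 2 (logLik_full - logLik_restricted)` referred to chi-square(df).
#' Used both for SDM reduction tests (df = k) and for comparing effects
#' specifications (two-way vs space-only: df = T; two-way vs time-only:
#' df = n).
#'
#' @param restricted,full Nested `panel_fit`s on the same data.
#' @param df Degrees of freedom of the restriction.
#' @param name Label for the result.
#' @param alpha Decision level (default 0.1).
#' @return A `spatial_test`.
#' @export
lr_test <- function(restricted, full, df, name = "LR", alpha = 0.1) {
  stat <- 2 * (full$loglik - restricted$loglik)
  if (stat < -1e-6) {
    stop("full model has lower likelihood than restricted (", format(stat),
         "): models not nested or optimizer failure")
  }
  stat <- max(0, stat)
  new_test_result(name, stat, df,
                  stats::pchisq(stat, df = df, lower.tail = FALSE), alpha)
}

#' Hausman test of fixed versus random effects
#'
#' Contrasts the common slope vector of a fixed-effects fit (consistent
#' under correlation between unit effects and covariates, inefficient
#' under none) with its random-effects counterpart:
#' `H = d' (V_FE - V_RE)^-1 d` on `d = b_FE - b_RE` over beta (and theta
#' for SDM); the spatial coefficient is excluded. As in the classical
#' panel construction, the slope covariances are the conditional
#' (GLS-form) ones `sigma2 (Z'Z)^-1` of each estimator, under which the
#' within/quasi-demeaned moment-matrix ordering keeps the difference
#' positive definite; a residual non-positive-definite difference is
#' handled by pseudo-inverse on its positive eigenspace and flagged.
#'
#' @param fe,re `panel_fit`s of the same model and covariates, one with
#'   fixed effects and one with `effects = "random"`.
#' @param alpha Decision level (default 0.1).
#' @return A `spatial_test` with df = length of the compared slope vector.
#' @export
hausman_test <- function(fe, re, alpha = 0.1) {
  stopifnot(inherits(fe, "panel_fit"), inherits(re, "panel_fit"))
  if (fe$model != re$model) stop("fits compare different models")
  common <- c(names(fe$beta), names(fe$theta))
  if (!all(common %in% c(names(re$beta), names(re$theta)))) {
    stop("fixed- and random-effects fits have different covariates")
  }
  d <- c(fe$beta, fe$theta) - c(re$beta, re$theta)[common]
  Vfe <- (fe$vcov_cond %||% fe$vcov)[common, common]
  Vre <- (re$vcov_cond %||% re$vcov)[common, common]
  Vd <- Vfe - Vre
  Vd <- (Vd + t(Vd)) / 2
  ev <- eigen(Vd, symmetric = TRUE)
  note <- NULL
  keep <- ev$values > 1e-10 * max(abs(ev$values))
  if (all(keep)) {
    stat <- drop(crossprod(d, solve(Vd, d)))
    df <- length(d)
  } else if (!any(keep)) {
    # degenerate: identical estimators (or a zero variance difference)
    return(new_test_result("Hausman FE vs RE", 0, length(d), 1, alpha,
                           "zero variance difference; trivial keep H0"))
  } else {
    # Moore-Penrose form on the positive eigenspace of the variance
    # difference; df = its rank
    proj <- crossprod(ev$vectors[, keep, drop = FALSE], d)
    stat <- sum(proj^2 / ev$values[keep])
    df <- sum(keep)
    note <- paste("variance difference not positive definite;",
                  "pseudo-inverse on its positive eigenspace, rank", df)
  }
  stat <- max(0, stat)
  new_test_result("Hausman FE vs RE", stat, df,
                  stats::pchisq(stat, df = df, lower.tail = FALSE),
                  alpha, note)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing covariate
#' k on all others (with intercept). Values above 10 conventionally signal
#' multicollinearity; exactly collinear columns get an infinite VIF and a
#' diagnostic flag.
#'
#' @param X Numeric matrix or data frame with at least 2 named covariate
#'   columns.
#' @return Data frame with columns `covariate`, `vif`, `flag`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("VIF needs at least 2 covariates")
  out <- data.frame(covariate = colnames(X), vif = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  for (k in seq_len(ncol(X))) {
    yk <- X[, k]
    Zk <- cbind(1, X[, -k, drop = FALSE])
    res <- yk - Zk %*% qr.coef(qr(Zk), yk)
    tss <- sum((yk - mean(yk))^2)
    if (tss == 0) { out$vif[k] <- Inf; out$flag[k] <- "constant"; next }
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) {
      out$vif[k] <- Inf
      out$flag[k] <- "exact collinearity"
    } else {
      out$vif[k] <- 1 / (1 - r2)
      if (out$vif[k] > 10) out$flag[k] <- "VIF > 10"
    }
  }
  out
}
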
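#' Balanced region-by-year panel container
#'
#' Holds the outcome and covariates of a balanced panel as n-by-T matrices
#' sharing one region ordering, the layout every estimator in the package
#' consumes. Unbalanced panels are rejected, not imputed.
#'
#' @param y Numeric n-by-T outcome matrix (regions in rows).
#' @param X Named list of n-by-T covariate matrices (k >= 1).
#' @param regions A `region_set` (or character ids) for the rows.
#' @param times Ordered vector of time labels (length T).
#' @return A `panel_data` object.
#' @seealso [panel_from_long()] for building from a long table.
#' @export
panel_data <- function(y, X, regions, times) {
  regions <- as_region_set(regions)
  y <- as.matrix(y)
  if (!is.list(X) || is.null(names(X)) || any(names(X) == "")) {
    stop("X must be a named list of covariate matrices")
  }
  X <- lapply(X, as.matrix)
  n <- regions$n
  T_ <- length(times)
  if (!all(dim(y) == c(n, T_))) {
    stop("y must be ", n, " x ", T_, " (regions x times)")
  }
  for (nm in names(X)) {
    if (!all(dim(X[[nm]]) == c(n, T_))) {
      stop("covariate '", nm, "' is not ", n, " x ", T_)
    }
  }
  if (anyNA(y) || any(vapply(X, anyNA, TRUE))) {
    stop("panel has missing cells; balanced complete panels are required")
  }
  dimnames(y) <- list(regions$ids, times)
  X <- lapply(X, function(m) { dimnames(m) <- dimnames(y); m })
  structure(list(regions = regions, times = times, y = y, X = X,
                 k = length(X)),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("<panel_data> n =", x$regions$n, " T =", length(x$times),
      " covariates:", paste(names(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Build a panel from a long table
#'
#' @param df Data frame in long format.
#' @param unit,time Column names of the unit and time keys.
#' @param outcome Column name of the outcome.
#' @param covariates Character vector of covariate column names.
#' @param regions Optional `region_set` fixing row order (default: sorted
#'   unique units).
#' @return A `panel_data` object; errors if any unit-time cell is missing
#'   or duplicated.
#' @export
panel_from_long <- function(df, unit = "unit_id", time = "year",
                            outcome = "y", covariates, regions = NULL) {
  need <- c(unit, time, outcome, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(regions)) regions <- region_set(sort(unique(df[[unit]])))
  times <- sort(unique(df[[time]]))
  i <- match(df[[unit]], regions$ids)
  t <- match(df[[time]], times)
  if (anyNA(i)) stop("unit id(s) outside the region set")
  idx <- cbind(i, t)
  if (anyDuplicated(idx)) stop("duplicated unit-time cell(s) in long table")
  if (nrow(df) != regions$n * length(times)) {
    stop("panel is unbalanced: expected ", regions$n * length(times),
         " rows, got ", nrow(df))
  }
  fill <- function(col) {
    m <- matrix(NA_real_, regions$n, length(times))
    m[idx] <- df[[col]]
    m
  }
  X <- lapply(covariates, fill)
  names(X) <- covariates
  panel_data(fill(outcome), X, regions, times)
}

# within transformations on an n x T matrix
demean_matrix <- function(m, effects) {
  switch(effects,
    pooled = m,
    space  = m - rowMeans(m),
    time   = sweep(m, 2L, colMeans(m)),
    both   = {
      g <- mean(m)
      m - rowMeans(m) - rep(colMeans(m), each = nrow(m)) + g
    },
    stop("unknown effects spec: ", effects)
  )
}

# number of linearly independent mean parameters absorbed by demeaning
fe_dof <- function(effects, n, T_) {
  switch(effects,
    pooled = 0L, space = n, time = T_, both = n + T_ - 1L)
}

#' Within (fixed-effects) panel least squares
#'
#' Demeans the outcome and covariates per the effects specification and
#' runs pooled OLS on the transformed data. This is the baseline model for
#' the Lagrange-multiplier spatial tests and the reference point of the
#' likelihood-ratio comparisons.
#'
#' @param panel A `panel_data` object.
#' @param effects One of `"pooled"`, `"space"` (unit effects), `"time"`,
#'   `"both"` (two-way).
#' @param bias_correct Book-keep the likelihood on the effective sample
#'   implied by the demeaning (unit demeaning: n(T-1) observations;
#'   two-way: (n-1)(T-1)), matching the default of
#'   [fit_spatial_panel()] so that nested likelihoods are comparable;
#'   `FALSE` uses the naive NT-observation likelihood.
#' @return A `panel_fit` with `model = "OLS"`: coefficients `beta`,
#'   `sigma2` (ML on the effective sample) and `sigma2_adj`
#'   (degrees-of-freedom corrected), `loglik`, `vcov`, residual matrix
#'   `resid` (n x T), and the demeaned design kept for downstream score
#'   tests.
#' @export
fit_panel_ols <- function(panel, effects = c("both", "space", "time",
                                             "pooled"),
                          bias_correct = TRUE) {
  effects <- match.arg(effects)
  stopifnot(inherits(panel, "panel_data"))
  n <- panel$regions$n
  T_ <- length(panel$times)
  ydm <- demean_matrix(panel$y, effects)
  Xdm <- lapply(panel$X, demean_matrix, effects = effects)
  Z <- vapply(Xdm, as.vector, numeric(n * T_))
  colnames(Z) <- names(panel$X)
  if (effects == "pooled") {
    Z <- cbind(`(Intercept)` = 1, Z)
  }
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    dropped <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1L):ncol(Z)]]
    stop("rank-deficient design after '", effects, "' demeaning; ",
         "collinear column(s): ", paste(dropped, collapse = ", "))
  }
  ysv <- as.vector(ydm)
  beta <- qr.coef(qrZ, ysv)
  res <- ysv - drop(Z %*% beta)
  NT <- n * T_
  sse <- sum(res^2)
  neff <- if (bias_correct && effects %in% c("time", "both")) n - 1L else n
  Teff <- if (bias_correct && effects %in% c("space", "both")) T_ - 1L
          else T_
  NTeff <- neff * Teff
  sigma2 <- sse / NTeff
  dof <- NT - fe_dof(effects, n, T_) - ncol(Z)
  sigma2_adj <- sse / dof
  loglik <- -NTeff / 2 * (log(2 * pi * sigma2) + 1)
  vcov <- sigma2_adj * chol2inv(qr.R(qrZ))
  dimnames(vcov) <- list(colnames(Z), colnames(Z))
  structure(list(
    model = "OLS", effects = effects,
    beta = stats::setNames(beta, colnames(Z)),
    rho = NULL, lambda = NULL, theta = NULL,
    sigma2 = sigma2, sigma2_adj = sigma2_adj,
    loglik = loglik, vcov = vcov, vcov_cond = vcov,
    resid = matrix(res, n, T_, dimnames = dimnames(panel$y)),
    fitted = matrix(drop(Z %*% beta), n, T_),
    panel = panel, demeaned = list(y = ydm, X = Xdm, Z = Z),
    n = n, T = T_, neff = neff, Teff = Teff,
    bias_correct = bias_correct, converged = TRUE
  ), class = "panel_fit")
}

#' @export
print.panel_fit <- function(x, ...) {
  cat(sprintf("<panel_fit> %s, %s effects  logLik = %.3f  sigma2 = %.4g\n",
              x$model, x$effects, x$loglik, x$sigma2))
  if (!is.null(x$rho)) cat(sprintf("  rho    = %.4f\n", x$rho))
  if (!is.null(x$lambda)) cat(sprintf("  lambda = %.4f\n", x$lambda))
  cat("  coefficients:\n")
  print(round(coef_table(x), 4))
  invisible(x)
}

#' Coefficient table of a panel fit
#'
#' @param fit A `panel_fit`.
#' @return Data frame with estimate, std. error, z and p per parameter
#'   (slopes, spatial-lag slopes, and rho/lambda where present).
#' @export
coef_table <- function(fit) {
  est <- c(fit$beta, fit$theta,
           if (!is.null(fit$rho)) c(rho = fit$rho),
           if (!is.null(fit$lambda)) c(lambda = fit$lambda))
  se <- sqrt(diag(fit$vcov))[names(est)]
  z <- est / se
  data.frame(estimate = est, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = names(est))
}
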
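# Eigenvalues of the (possibly row-standardized) weight matrix. For a
# row-standardized matrix derived from a symmetric binary W0, W = D^-1 W0
# is similar to the symmetric D^-1/2 W0 D^-1/2, so the spectrum is real.
w_eigenvalues <- function(w, binary = FALSE) {
  if (binary || !w$standardized) {
    return(eigen(w$W0, symmetric = TRUE, only.values = TRUE)$values)
  }
  d <- rowSums(w$W0)
  S <- w$W0 / sqrt(outer(d, d))
  eigen(S, symmetric = TRUE, only.values = TRUE)$values
}

rho_interval <- function(omega, shrink = 1e-6) {
  lo <- if (min(omega) < 0) 1 / min(omega) else -1 + shrink
  hi <- if (max(omega) > 0) 1 / max(omega) else 1 - shrink
  c(lo + shrink, hi - shrink)
}

# Transformation bookkeeping for fixed-effects estimation. Demeaning over
# time (unit effects) leaves T-1 effective periods; removing time effects
# is handled by an orthonormal rotation of the cross-section onto the
# complement of the constant vector, under which the row-stochastic W
# (W1 = 1) reduces to an (n-1)x(n-1) matrix whose spectrum is W's with
# one unit eigenvalue removed. Estimating on the rotated data removes the
# incidental-parameter bias the naive demeaned likelihood carries.
fe_transform <- function(effects, bias_correct, Wm, omega, n, T_) {
  proj_n <- bias_correct && effects %in% c("time", "both")
  Teff <- if (bias_correct && effects %in% c("space", "both")) T_ - 1L
          else T_
  if (proj_n) {
    Fq <- qr.Q(qr(matrix(1, n, 1L)), complete = TRUE)[, -1L, drop = FALSE]
    Wuse <- crossprod(Fq, Wm %*% Fq)
    drop_i <- which.min(abs(omega - 1))
    omega_use <- omega[-drop_i]
    rotate <- function(m) crossprod(Fq, m)
    neff <- n - 1L
  } else {
    Wuse <- Wm
    omega_use <- omega
    rotate <- identity
    neff <- n
  }
  list(Wuse = Wuse, omega = omega_use, rotate = rotate,
       neff = neff, Teff = Teff, NTeff = neff * Teff)
}

#' Maximum-likelihood spatial panel estimation (SAR / SEM / SDM)
#'
#' Fits a spatial panel model by concentrated maximum likelihood on a
#' balanced panel. With `y_t` the n-vector of outcomes in period t:
#'
#' * SAR: `y_t = rho W y_t + X_t beta + effects + eps_t`
#' * SEM: `y_t = X_t beta + effects + u_t`, `u_t = lambda W u_t + eps_t`
#' * SDM: `y_t = rho W y_t + X_t beta + W X_t theta + effects + eps_t`
#'
#' Fixed effects are removed by within-demeaning (`"space"`, `"time"`,
#' `"both"` = two-way). With `bias_correct = TRUE` (default) the
#' likelihood is evaluated on the orthonormally transformed data with the
#' effective dimensions (unit demeaning: T-1 periods; time demeaning:
#' n-1 rotated units and one unit eigenvalue of W dropped from the
#' log-determinant), which removes the incidental-parameter bias of the
#' naive demeaned likelihood; `bias_correct = FALSE` reproduces the
#' classical direct-demeaning likelihood on all NT observations, whose
#' values are the conventional basis for likelihood-ratio comparisons
#' between effects specifications.
#'
#' `"random"` effects (SAR/SDM) use one-way unit random effects estimated
#' by ML with the quasi-demeaning weight profiled jointly with rho.
#'
#' The log-determinant term uses the precomputed eigenvalues of W, and
#' the spatial coefficient is searched on the eigenvalue-bounded interval
#' with a coarse grid to bracket the optimum before refinement. The
#' parameter covariance comes from the analytic information matrix (fixed
#' effects) or a numerical Hessian of the full likelihood (random
#' effects).
#'
#' @param panel A `panel_data` object.
#' @param w Row-standardized `spatial_weights` sharing the panel's regions.
#' @param model `"SAR"`, `"SEM"` or `"SDM"`.
#' @param effects `"both"` (default), `"space"`, `"time"`, `"pooled"`, or
#'   `"random"`.
#' @param bias_correct Use the transformed-likelihood bookkeeping
#'   (default `TRUE`).
#' @param grid_points Coarse-grid size for bracketing the spatial
#'   coefficient (default 50).
#' @return A `panel_fit` with `beta`, `theta` (SDM), `rho` or `lambda`,
#'   `sigma2` (ML on the effective sample), `sigma2_adj`
#'   (degrees-of-freedom corrected), `loglik`, `vcov`, residuals, and a
#'   `boundary` flag when the spatial coefficient sits within 1e-4 of the
#'   search interval's edge.
#' @export
fit_spatial_panel <- function(panel, w,
                              model = c("SDM", "SAR", "SEM"),
                              effects = c("both", "space", "time",
                                          "pooled", "random"),
                              bias_correct = TRUE,
                              grid_points = 50L) {
  model <- match.arg(model)
  effects <- match.arg(effects)
  stopifnot(inherits(panel, "panel_data"), inherits(w, "spatial_weights"))
  if (!identical(w$regions$ids, panel$regions$ids)) {
    stop("weights and panel must share the same region ordering")
  }
  if (!w$standardized) {
    warning("weights are not row-standardized; standardizing now")
    w <- row_standardize(w)
  }
  if (effects == "random") {
    if (model == "SEM") stop("random effects are implemented for SAR/SDM")
    return(fit_spatial_panel_re(panel, w, model, grid_points))
  }
  Wm <- w$W
  omega <- w_eigenvalues(w)
  interval <- rho_interval(omega)
  n <- panel$regions$n
  T_ <- length(panel$times)
  tr <- fe_transform(effects, bias_correct, Wm, omega, n, T_)

  ydm <- tr$rotate(demean_matrix(panel$y, effects))
  Xdm <- lapply(panel$X, function(m) tr$rotate(demean_matrix(m, effects)))
  xnames <- names(panel$X)
  NTobs <- tr$neff * T_          # rows of the stacked design
  Z <- vapply(Xdm, as.vector, numeric(NTobs))
  colnames(Z) <- xnames
  if (model == "SDM") {
    ZW <- vapply(Xdm, function(m) as.vector(tr$Wuse %*% m),
                 numeric(NTobs))
    colnames(ZW) <- paste0("W.", xnames)
    Z <- cbind(Z, ZW)
  }
  if (effects == "pooled") Z <- cbind(`(Intercept)` = 1, Z)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    stop("rank-deficient regressor matrix (collinear covariates or their ",
         "spatial lags)")
  }
  ysv <- as.vector(ydm)
  p <- ncol(Z)

  if (model == "SEM") {
    fit <- sem_concentrated_fit(ydm, Xdm, tr, interval, effects,
                                grid_points, xnames)
  } else {
    Wy <- as.vector(tr$Wuse %*% ydm)
    b0 <- qr.coef(qrZ, ysv); e0 <- ysv - drop(Z %*% b0)
    b1 <- qr.coef(qrZ, Wy);  e1 <- Wy - drop(Z %*% b1)
    cll <- function(rho) {
      ee <- sum((e0 - rho * e1)^2)
      -tr$NTeff / 2 * log(ee / tr$NTeff) +
        tr$Teff * sum(log1p(-rho * tr$omega))
    }
    rho_hat <- maximize_scalar(cll, interval, grid_points)
    delta <- b0 - rho_hat * b1
    res <- e0 - rho_hat * e1
    sse <- sum(res^2)
    sigma2 <- sse / tr$NTeff
    sigma2_adj <- sse / max(tr$NTeff - p - 1L, 1L)
    loglik <- -tr$NTeff / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2) +
      tr$Teff * sum(log1p(-rho_hat * tr$omega))
    vcov <- sar_information_vcov(Z, delta, rho_hat, sigma2_adj, tr)
    vcov_cond <- sigma2_adj * chol2inv(qr.R(qrZ))
    dimnames(vcov_cond) <- list(colnames(Z), colnames(Z))
    fit <- list(delta = delta, rho = rho_hat, lambda = NULL,
                sigma2 = sigma2, sigma2_adj = sigma2_adj,
                loglik = loglik, vcov = vcov, vcov_cond = vcov_cond,
                resid = res)
  }

  sp <- if (model == "SEM") fit$lambda else fit$rho
  boundary <- !is.null(sp) && min(abs(sp - interval)) < 1e-4

  delta <- fit$delta
  if (model == "SDM") {
    is_theta <- grepl("^W\\.", names(delta))
    beta <- delta[!is_theta]
    theta <- delta[is_theta]
  } else {
    beta <- delta
    theta <- NULL
  }
  structure(list(
    model = model, effects = effects, bias_correct = bias_correct,
    beta = beta, theta = theta, rho = fit$rho, lambda = fit$lambda,
    sigma2 = fit$sigma2, sigma2_adj = fit$sigma2_adj,
    loglik = fit$loglik, vcov = fit$vcov, vcov_cond = fit$vcov_cond,
    resid = matrix(fit$resid, tr$neff, T_),
    panel = panel, w = w, interval = interval,
    n = n, T = T_, neff = tr$neff, Teff = tr$Teff,
    converged = TRUE, boundary = boundary
  ), class = "panel_fit")
}

# coarse grid then refinement inside the bracketing cell
maximize_scalar <- function(f, interval, grid_points) {
  grid <- seq(interval[1L], interval[2L], length.out = grid_points)
  vals <- vapply(grid, f, 0)
  if (all(!is.finite(vals))) stop("non-convergence: likelihood not finite ",
                                  "anywhere on the coarse grid")
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_points, i + 1L)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
}

# analytic information matrix for SAR/SDM; param order (delta, rho, sigma2)
sar_information_vcov <- function(Z, delta, rho, sigma2, tr) {
  neff <- tr$neff
  G <- tr$Wuse %*% solve(diag(neff) - rho * tr$Wuse)
  p_mat <- matrix(drop(Z %*% delta), neff)
  Gp <- as.vector(G %*% p_mat)
  trG <- sum(diag(G))
  trGG <- sum(G * t(G))
  trGtG <- sum(G * G)
  p <- ncol(Z)
  info <- matrix(0, p + 2L, p + 2L)
  info[1:p, 1:p] <- crossprod(Z) / sigma2
  info[1:p, p + 1L] <- info[p + 1L, 1:p] <- crossprod(Z, Gp) / sigma2
  info[p + 1L, p + 1L] <- tr$Teff * (trGG + trGtG) + sum(Gp^2) / sigma2
  info[p + 1L, p + 2L] <- info[p + 2L, p + 1L] <- tr$Teff * trG / sigma2
  info[p + 2L, p + 2L] <- tr$NTeff / (2 * sigma2^2)
  vcov <- solve(info)
  nm <- c(colnames(Z), "rho", "sigma2")
  dimnames(vcov) <- list(nm, nm)
  vcov
}

sem_concentrated_fit <- function(ydm, Xdm, tr, interval, effects,
                                 grid_points, xnames) {
  neff <- tr$neff
  NTobs <- length(ydm)
  fit_at <- function(lambda) {
    B <- diag(neff) - lambda * tr$Wuse
    ys <- as.vector(B %*% ydm)
    Zs <- vapply(Xdm, function(m) as.vector(B %*% m), numeric(NTobs))
    if (effects == "pooled") Zs <- cbind(1, Zs)
    qz <- qr(Zs)
    b <- qr.coef(qz, ys)
    e <- ys - drop(Zs %*% b)
    list(b = b, e = e, sse = sum(e^2), Zs = Zs)
  }
  cll <- function(lambda) {
    -tr$NTeff / 2 * log(fit_at(lambda)$sse / tr$NTeff) +
      tr$Teff * sum(log1p(-lambda * tr$omega))
  }
  lambda_hat <- maximize_scalar(cll, interval, grid_points)
  at <- fit_at(lambda_hat)
  sigma2 <- at$sse / tr$NTeff
  p <- length(at$b)
  sigma2_adj <- at$sse / max(tr$NTeff - p - 1L, 1L)
  loglik <- -tr$NTeff / 2 * log(2 * pi * sigma2) - at$sse / (2 * sigma2) +
    tr$Teff * sum(log1p(-lambda_hat * tr$omega))
  G <- tr$Wuse %*% solve(diag(neff) - lambda_hat * tr$Wuse)
  trG <- sum(diag(G)); trGG <- sum(G * t(G)); trGtG <- sum(G * G)
  info <- matrix(0, p + 2L, p + 2L)
  info[1:p, 1:p] <- crossprod(at$Zs) / sigma2_adj
  info[p + 1L, p + 1L] <- tr$Teff * (trGG + trGtG)
  info[p + 1L, p + 2L] <- info[p + 2L, p + 1L] <- tr$Teff * trG / sigma2_adj
  info[p + 2L, p + 2L] <- tr$NTeff / (2 * sigma2_adj^2)
  vcov <- solve(info)
  cn <- if (effects == "pooled") c("(Intercept)", xnames) else xnames
  nm <- c(cn, "lambda", "sigma2")
  dimnames(vcov) <- list(nm, nm)
  vcov_cond <- sigma2_adj * solve(crossprod(at$Zs))
  dimnames(vcov_cond) <- list(cn, cn)
  delta <- stats::setNames(at$b, cn)
  list(delta = delta, rho = NULL, lambda = lambda_hat, sigma2 = sigma2,
       sigma2_adj = sigma2_adj, loglik = loglik, vcov = vcov,
       vcov_cond = vcov_cond, resid = at$e)
}

# one-way unit random effects by ML: quasi-demeaning weight phi profiled
# jointly with rho; phi = 1 - sigma_eps / sqrt(sigma_eps^2 + T sigma_mu^2)
fit_spatial_panel_re <- function(panel, w, model, grid_points) {
  Wm <- w$W
  omega <- w_eigenvalues(w)
  interval <- rho_interval(omega)
  n <- panel$regions$n
  T_ <- length(panel$times)
  NT <- n * T_
  xnames <- names(panel$X)

  build <- function(phi) {
    qd <- function(m) m - phi * rowMeans(m)
    yq <- qd(panel$y)
    Xq <- lapply(panel$X, qd)
    Z <- vapply(Xq, as.vector, numeric(NT))
    colnames(Z) <- xnames
    if (model == "SDM") {
      ZW <- vapply(Xq, function(m) as.vector(Wm %*% m), numeric(NT))
      colnames(ZW) <- paste0("W.", xnames)
      Z <- cbind(Z, ZW)
    }
    Z <- cbind(`(Intercept)` = 1 - phi, Z)
    list(ysv = as.vector(yq), Wy = as.vector(Wm %*% yq), Z = Z)
  }
  cll <- function(par) {
    rho <- par[1L]; phi <- par[2L]
    if (rho <= interval[1L] || rho >= interval[2L] ||
        phi < 0 || phi >= 1) return(-Inf)
    d <- build(phi)
    b <- qr.coef(qr(d$Z), d$ysv - rho * d$Wy)
    e <- d$ysv - rho * d$Wy - drop(d$Z %*% b)
    -NT / 2 * log(sum(e^2) / NT) + n * log1p(-phi) +
      T_ * sum(log1p(-rho * omega))
  }
  # coarse grid to start, then box-constrained refinement
  rg <- seq(interval[1L] + 0.02, interval[2L] - 0.02, length.out = 12L)
  pg <- seq(0, 0.95, length.out = 12L)
  grid <- as.matrix(expand.grid(rho = rg, phi = pg))
  vals <- apply(grid, 1L, cll)
  start <- grid[which.max(vals), ]
  opt <- stats::optim(start, function(p) -cll(p), method = "L-BFGS-B",
                      lower = c(interval[1L] + 1e-5, 0),
                      upper = c(interval[2L] - 1e-5, 0.999),
                      control = list(factr = 1e7))
  rho_hat <- opt$par[1L]; phi_hat <- opt$par[2L]
  d <- build(phi_hat)
  qz <- qr(d$Z)
  delta <- qr.coef(qz, d$ysv - rho_hat * d$Wy)
  res <- d$ysv - rho_hat * d$Wy - drop(d$Z %*% delta)
  sse <- sum(res^2)
  sigma2 <- sse / NT
  loglik <- -NT / 2 * log(2 * pi * sigma2) - sse / (2 * sigma2) +
    n * log1p(-phi_hat) + T_ * sum(log1p(-rho_hat * omega))

  # numerical Hessian of the full likelihood over (delta, rho, phi, sigma2)
  full_ll <- function(par) {
    p <- ncol(d$Z)
    del <- par[1:p]; rho <- par[p + 1L]; phi <- par[p + 2L]
    s2 <- par[p + 3L]
    if (s2 <= 0 || phi < 0 || phi >= 1 ||
        rho <= interval[1L] || rho >= interval[2L]) return(-Inf)
    dd <- build(phi)
    e <- dd$ysv - rho * dd$Wy - drop(dd$Z %*% del)
    -NT / 2 * log(2 * pi * s2) - sum(e^2) / (2 * s2) + n * log1p(-phi) +
      T_ * sum(log1p(-rho * omega))
  }
  par_hat <- c(delta, rho_hat, phi_hat, sigma2)
  H <- stats::optimHess(par_hat, function(p) -full_ll(p))
  vcov <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  nm <- c(colnames(d$Z), "rho", "phi", "sigma2")
  dimnames(vcov) <- list(nm, nm)
  vcov_cond <- sigma2 * chol2inv(qr.R(qz))
  dimnames(vcov_cond) <- list(colnames(d$Z), colnames(d$Z))
  delta <- stats::setNames(delta, colnames(d$Z))
  is_theta <- grepl("^W\\.", names(delta))
  is_int <- names(delta) == "(Intercept)"
  structure(list(
    model = model, effects = "random", bias_correct = FALSE,
    beta = delta[!is_theta & !is_int],
    theta = if (model == "SDM") delta[is_theta] else NULL,
    intercept = delta[["(Intercept)"]],
    rho = rho_hat, lambda = NULL, phi = phi_hat,
    sigma2 = sigma2, sigma2_adj = sigma2,
    loglik = loglik, vcov = vcov, vcov_cond = vcov_cond,
    resid = matrix(res, n, T_, dimnames = dimnames(panel$y)),
    panel = panel, w = w, interval = interval,
    n = n, T = T_, neff = n, Teff = T_,
    converged = opt$convergence == 0,
    boundary = min(abs(rho_hat - interval)) < 1e-4
  ), class = "panel_fit")
}
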
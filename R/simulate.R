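#' Rook edge list of an r-by-c lattice
#'
#' Regular grids give weight matrices with known structure, convenient for
#' simulation studies: an r-by-c grid of unit cells has exactly
#' `r(c-1) + c(r-1)` rook adjacencies.
#'
#' @param rows,cols Grid dimensions (each >= 2).
#' @return Two-column character matrix of edges; cell ids are `"r_c"`.
#' @export
make_lattice <- function(rows, cols) {
  if (rows < 2L || cols < 2L) stop("lattice needs rows >= 2 and cols >= 2")
  id <- function(r, c) paste0(r, "_", c)
  edges <- list()
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) edges[[length(edges) + 1L]] <- c(id(r, c), id(r, c + 1L))
      if (r < rows) edges[[length(edges) + 1L]] <- c(id(r, c), id(r + 1L, c))
    }
  }
  do.call(rbind, edges)
}

#' Row-standardized lattice weights
#' @param rows,cols Grid dimensions.
#' @return A standardized `spatial_weights` over the grid cells.
#' @export
lattice_weights <- function(rows, cols) {
  ids <- as.vector(outer(seq_len(rows), seq_len(cols),
                         function(r, c) paste0(r, "_", c)))
  row_standardize(build_rook_from_edges(make_lattice(rows, cols),
                                        region_set(ids)))
}

#' Configuration for the spatial Durbin data-generating process
#'
#' Describes a balanced panel whose outcome follows the SDM reduced form
#' `y_t = (I - rho W)^-1 (alpha + X_t beta + W X_t theta + mu + nu_t 1 +
#' eps_t)` with unit effects `mu` (optionally correlated with the
#' covariates' unit means, the channel that makes pooled OLS biased and
#' fixed effects necessary), time effects `nu_t`, and iid normal noise.
#'
#' @param n_units,T_periods Panel dimensions.
#' @param rho True spatial autoregressive coefficient, |rho| < 1.
#' @param beta,theta True covariate and spatial-lag-covariate coefficients
#'   (equal length k).
#' @param sigma Error standard deviation (> 0).
#' @param fe_unit_sd,fe_time_sd Standard deviations of the unit and time
#'   effects (0 disables them).
#' @param fe_x_corr Correlation between the unit effects and the unit-level
#'   covariate means, in [0, 1).
#' @param x_sd Covariate standard deviations (recycled to k).
#' @param x_ar1 Optional AR(1) coefficient for covariate evolution over
#'   time (0 = iid around unit means; 0.8 emulates slow-moving regional
#'   covariates).
#' @param alpha Intercept.
#' @param x_names Covariate names (default x1..xk).
#' @return An `sdm_dgp_config` list, validated.
#' @export
sdm_dgp_config <- function(n_units = 31L, T_periods = 8L, rho = 0.4,
                           beta = c(1, -0.5), theta = c(0.3, 0),
                           sigma = 1, fe_unit_sd = 1, fe_time_sd = 0.5,
                           fe_x_corr = 0, x_sd = 1, x_ar1 = 0,
                           alpha = 0, x_names = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(beta) != length(theta)) {
    stop("beta and theta must have the same length")
  }
  k <- length(beta)
  # fe_x_corr is the correlation between the unit effect and EACH
  # covariate's unit-level mean; with k independent covariates it cannot
  # exceed 1/sqrt(k)
  if (fe_x_corr < 0 || fe_x_corr > 1 / sqrt(k)) {
    stop("fe_x_corr must be in [0, 1/sqrt(k)] = [0, ",
         round(1 / sqrt(k), 4), "] for k = ", k, " covariates")
  }
  if (is.null(x_names)) x_names <- paste0("x", seq_len(k))
  structure(list(n_units = as.integer(n_units),
                 T_periods = as.integer(T_periods),
                 rho = rho, beta = stats::setNames(beta, x_names),
                 theta = stats::setNames(theta, paste0("W.", x_names)),
                 sigma = sigma, fe_unit_sd = fe_unit_sd,
                 fe_time_sd = fe_time_sd, fe_x_corr = fe_x_corr,
                 x_sd = rep_len(x_sd, k), x_ar1 = x_ar1, alpha = alpha,
                 k = k, x_names = x_names),
            class = "sdm_dgp_config")
}

#' Simulate a balanced panel from the SDM data-generating process
#'
#' @param w Row-standardized `spatial_weights`; its region count must match
#'   `cfg$n_units`.
#' @param cfg An [sdm_dgp_config()].
#' @param seed RNG seed; the output is fully determined by it.
#' @return List with `panel` (a `panel_data`) and `truth` (the generating
#'   parameters including the drawn `mu` and `nu` vectors).
#' @export
simulate_sdm_panel <- function(w, cfg, seed) {
  stopifnot(inherits(w, "spatial_weights"), inherits(cfg, "sdm_dgp_config"))
  if (!w$standardized) stop("weights must be row-standardized")
  n <- w$regions$n
  if (n != cfg$n_units) {
    stop("weights have ", n, " regions but config expects ", cfg$n_units)
  }
  T_ <- cfg$T_periods
  k <- cfg$k
  set.seed(seed)
  Wm <- w$W

  # unit-level covariate means; the unit effect shares a component with
  # them when fe_x_corr > 0, with corr(mu, xbar_j) = fe_x_corr for each j
  xbar <- matrix(stats::rnorm(n * k), n, k)
  mu_raw <- stats::rnorm(n)
  r <- cfg$fe_x_corr
  mu <- cfg$fe_unit_sd *
    (r * sqrt(k) * scale_unit(rowMeans(xbar)) +
       sqrt(max(0, 1 - k * r^2)) * mu_raw)
  nu <- if (cfg$fe_time_sd > 0) stats::rnorm(T_, sd = cfg$fe_time_sd)
        else numeric(T_)

  X <- vector("list", k)
  for (j in seq_len(k)) {
    m <- matrix(0, n, T_)
    if (cfg$x_ar1 > 0) {
      innov_sd <- cfg$x_sd[j] * sqrt(1 - cfg$x_ar1^2)
      m[, 1L] <- stats::rnorm(n, sd = cfg$x_sd[j])
      for (t in 2:T_) {
        m[, t] <- cfg$x_ar1 * m[, t - 1L] + stats::rnorm(n, sd = innov_sd)
      }
    } else {
      m[] <- stats::rnorm(n * T_, sd = cfg$x_sd[j])
    }
    X[[j]] <- m + xbar[, j]
  }
  names(X) <- cfg$x_names

  A_inv <- solve(diag(n) - cfg$rho * Wm)
  y <- matrix(0, n, T_)
  for (t in seq_len(T_)) {
    lin <- cfg$alpha + mu + nu[t]
    for (j in seq_len(k)) {
      lin <- lin + X[[j]][, t] * cfg$beta[j] +
        drop(Wm %*% X[[j]][, t]) * cfg$theta[j]
    }
    y[, t] <- drop(A_inv %*% (lin + stats::rnorm(n, sd = cfg$sigma)))
  }
  panel <- panel_data(y, X, w$regions, seq_len(T_))
  list(panel = panel,
       truth = list(rho = cfg$rho, beta = cfg$beta, theta = cfg$theta,
                    sigma = cfg$sigma, mu = mu, nu = nu, alpha = cfg$alpha,
                    seed = seed, config = cfg))
}

scale_unit <- function(v) (v - mean(v)) / stats::sd(v)

#' Simulate monthly search series with a controllable seasonal peak
#'
#' Monthly totals follow a base level modulated by a circular (von
#' Mises-shaped) bump centred on `peak_month`; `kappa = 0` makes months
#' exchangeable, larger `kappa` concentrates the annual volume into the
#' peak months, driving the concentration statistic M towards 1.
#'
#' @param years Vector of year labels.
#' @param peak_month Calendar month (1..12) of the seasonal peak.
#' @param kappa Concentration strength (>= 0).
#' @param base_level Expected monthly volume at kappa = 0.
#' @param noise_cv Multiplicative lognormal noise coefficient of variation
#'   (default 0.05).
#' @param seed RNG seed.
#' @return Data frame with columns `year`, `month`, `dbi`.
#' @export
simulate_monthly_series <- function(years, peak_month = 11L, kappa = 2,
                                    base_level = 1000, noise_cv = 0.05,
                                    seed = 1L) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!peak_month %in% 1:12) stop("peak_month must be in 1..12")
  set.seed(seed)
  ang <- 2 * pi * (1:12 - peak_month) / 12
  bump <- exp(kappa * cos(ang))
  bump <- bump / mean(bump)
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- lapply(years, function(y) {
    noise <- stats::rlnorm(12L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(year = y, month = 1:12, dbi = base_level * bump * noise)
  })
  do.call(rbind, out)
}

#' Blocky attribute vector for cluster-recovery fixtures
#'
#' Assigns mean `+effect` to a designated block of regions and `-effect`
#' to the rest, plus iid normal noise: the canonical input for checking
#' that LISA labels block interiors HH and the complement LL.
#'
#' @param w A `spatial_weights` object.
#' @param high_block Character ids of the high-mean block.
#' @param effect Half-distance between the block means.
#' @param noise_sd Noise standard deviation.
#' @param seed RNG seed.
#' @return Named numeric vector over `region_ids(w)`.
#' @export
make_blocky_attribute <- function(w, high_block, effect = 1, noise_sd = 0.2,
                                  seed = 1L) {
  stopifnot(inherits(w, "spatial_weights"))
  unknown <- setdiff(high_block, w$regions$ids)
  if (length(unknown)) {
    stop("block id(s) not in region set: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  base <- ifelse(w$regions$ids %in% high_block, effect, -effect)
  stats::setNames(base + stats::rnorm(w$regions$n, sd = noise_sd),
                  w$regions$ids)
}
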
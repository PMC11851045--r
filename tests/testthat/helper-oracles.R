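# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately mirror the definitions literally (double loops, full
# likelihood surfaces) rather than reusing the package's vectorized paths.

# literal double-sum global Moran's I
moran_double_loop <- function(x, Wm) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Wm[i, j] * z[i] * z[j]
      S0 <- S0 + Wm[i, j]
    }
  }
  (n / S0) * num / sum(z^2)
}

# random connected undirected graph over n nodes: a random spanning tree
# plus extra random edges
random_connected_weights <- function(n, extra = n, seed) {
  set.seed(seed)
  ids <- paste0("r", seq_len(n))
  perm <- sample(ids)
  edges <- cbind(perm[-1], perm[vapply(2:n, function(i)
    sample.int(i - 1L, 1L), 1L)])
  for (e in seq_len(extra)) {
    pair <- sample(ids, 2L)
    edges <- rbind(edges, pair)
  }
  w <- build_rook_from_edges(edges, region_set(ids))
  row_standardize(w)
}

# full (non-concentrated) cross-sectional SAR log-likelihood, maximized
# by general-purpose optimization -- the T = 1 equivalence oracle
sar_cross_section_brute <- function(y, X, Wm) {
  n <- length(y)
  Xd <- cbind(1, X)
  nll <- function(par) {
    rho <- par[1L]
    beta <- par[2:(ncol(Xd) + 1L)]
    lsig2 <- par[length(par)]
    s2 <- exp(lsig2)
    if (abs(rho) >= 0.999) return(1e10)
    A <- diag(n) - rho * Wm
    e <- A %*% y - Xd %*% beta
    -(as.numeric(determinant(A)$modulus) - n / 2 * log(2 * pi * s2) -
        sum(e^2) / (2 * s2))
  }
  start <- c(0, qr.coef(qr(Xd), y), log(stats::var(y)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(rho = opt$par[1L], beta = opt$par[2:(ncol(Xd) + 1L)],
       sigma2 = exp(opt$par[length(opt$par)]), nll = opt$value)
}

# independent concentrated SAR log-likelihood profile for two-way FE,
# computed through a different route than the package (explicit
# orthonormal rotation, lm() residuals, determinant() instead of
# eigenvalues); returns a function of rho
sar_concentrated_profile <- function(panel, w) {
  Wm <- w$W
  n <- panel$regions$n
  T_ <- length(panel$times)
  dm <- function(m) {
    g <- mean(m)
    m - rowMeans(m) - rep(colMeans(m), each = nrow(m)) + g
  }
  Fq <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  Ws <- t(Fq) %*% Wm %*% Fq
  y <- t(Fq) %*% dm(panel$y)
  Xl <- lapply(panel$X, function(m) t(Fq) %*% dm(m))
  Z <- do.call(cbind, lapply(Xl, as.vector))
  ysv <- as.vector(y)
  Wy <- as.vector(Ws %*% y)
  NTeff <- (n - 1) * (T_ - 1)
  function(rho) {
    e <- stats::lm.fit(Z, ysv - rho * Wy)$residuals
    ld <- as.numeric(determinant(diag(n - 1) - rho * Ws)$modulus)
    -NTeff / 2 * log(sum(e^2) / NTeff) + (T_ - 1) * ld
  }
}

# shared small fixtures
lattice44 <- function() lattice_weights(4, 4)

checkerboard44 <- function() {
  ids <- region_ids(lattice44())
  parity <- vapply(strsplit(ids, "_"), function(p) {
    (as.integer(p[1]) + as.integer(p[2])) %% 2L
  }, 0L)
  ifelse(parity == 0L, 1, -1)
}

expect_symmetric_zero_diag <- function(w) {
  expect_true(all(w$W0 == t(w$W0)))
  expect_true(all(diag(w$W0) == 0))
}
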
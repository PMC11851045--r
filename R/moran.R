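#' Global Moran's I with analytic and permutation inference
#'
#' Computes `I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)` and `S0 = sum_ij w_ij`, together with its null
#' expectation `E[I] = -1/(n-1)`, an analytic z-score (randomization or
#' normality variance), and optionally a permutation pseudo p-value.
#'
#' The permutation p is two-sided by folding around `E[I]`:
#' `p = (1 + #{|I_perm - E[I]| >= |I_obs - E[I]|}) / (n_perm + 1)`.
#'
#' @param x Numeric attribute vector, one value per region, in the order of
#'   `region_ids(w)`. Must not be constant.
#' @param w A `spatial_weights` object (row-standardized unless
#'   `binary = TRUE` weighting is wanted).
#' @param inference `"analytic_randomization"` (default),
#'   `"analytic_normality"`, or `"permutation"`; determines which p-value
#'   the `p` field reports. Analytic moments are always computed;
#'   permutation columns are filled whenever `n_perm > 0`.
#' @param n_perm Number of permutations for the pseudo p (default 999; 0
#'   skips permutation).
#' @param seed RNG seed for the permutations (required when `n_perm > 0`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`, for
#'   both analytic and permutation p-values.
#' @param binary Use the binary contiguity matrix instead of the
#'   row-standardized one.
#' @return A `moran_global` list: `I`, `expected_I`, `var_I`, `z`,
#'   `p_analytic`, `p_perm`, `n_perm`, `seed`, `inference`, `p`.
#' @export
global_moran <- function(x, w, inference = c("analytic_randomization",
                                             "analytic_normality",
                                             "permutation"),
                         n_perm = 999L, seed = NULL,
                         alternative = c("two.sided", "greater", "less"),
                         binary = FALSE) {
  inference <- match.arg(inference)
  alternative <- match.arg(alternative)
  stopifnot(inherits(w, "spatial_weights"))
  n <- w$regions$n
  if (length(x) != n) stop("attribute length ", length(x),
                           " does not match n = ", n)
  if (anyNA(x)) stop("missing attribute values")
  if (stats::var(x) == 0) stop("degenerate input: attribute is constant")
  Wm <- weights_matrix(w, binary = binary)
  z <- x - mean(x)
  ss <- sum(z^2)
  S0 <- sum(Wm)
  I <- (n / S0) * drop(z %*% Wm %*% z) / ss
  EI <- -1 / (n - 1)

  # analytic moments
  S1 <- 0.5 * sum((Wm + t(Wm))^2)
  S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
  if (inference == "analytic_normality") {
    varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / ss^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  zscore <- (I - EI) / sqrt(varI)
  p_analytic <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(zscore)),
    greater   = stats::pnorm(zscore, lower.tail = FALSE),
    less      = stats::pnorm(zscore)
  )

  p_perm <- NA_real_
  if (n_perm > 0L) {
    if (is.null(seed)) stop("seed is required for permutation inference")
    set.seed(seed)
    perm_I <- moran_perm_values(z, Wm, n, S0, ss, n_perm)
    p_perm <- switch(alternative,
      two.sided = (1 + sum(abs(perm_I - EI) >= abs(I - EI) - 1e-14)) /
        (n_perm + 1),
      greater = (1 + sum(perm_I >= I - 1e-14)) / (n_perm + 1),
      less = (1 + sum(perm_I <= I + 1e-14)) / (n_perm + 1)
    )
  } else if (inference == "permutation") {
    stop("inference = 'permutation' needs n_perm > 0")
  }

  structure(list(
    I = I, expected_I = EI, var_I = varI, z = zscore,
    p_analytic = p_analytic, p_perm = p_perm,
    n_perm = if (n_perm > 0L) as.integer(n_perm) else 0L,
    seed = seed, inference = inference, alternative = alternative,
    p = if (inference == "permutation") p_perm else p_analytic
  ), class = "moran_global")
}

# permuted Moran values, vectorized: each row of ZP is a permuted z
moran_perm_values <- function(z, Wm, n, S0, ss, n_perm) {
  ZP <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) ZP[b, ] <- z[sample.int(n)]
  (n / S0) * rowSums((ZP %*% t(Wm)) * ZP) / ss
}

#' @export
print.moran_global <- function(x, ...) {
  cat(sprintf("<moran_global> I = %.4f  E[I] = %.4f  z = %.3f\n",
              x$I, x$expected_I, x$z))
  cat(sprintf("  p (%s) = %.4g", x$inference, x$p))
  if (!is.na(x$p_perm) && x$inference != "permutation") {
    cat(sprintf("   p_perm(%d) = %.4g", x$n_perm, x$p_perm))
  }
  cat("\n")
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' Per-unit statistic `I_i = (z_i / m2) * sum_j w_ij z_j` with
#' `m2 = sum_k z_k^2 / n`. Each unit is assigned a Moran-scatterplot
#' quadrant from the signs of its deviation and its spatial lag: HH, LL
#' (clusters) or HL, LH (outliers). Significance uses conditional
#' permutation: unit i's value is held fixed and the remaining values are
#' permuted into its neighbours' positions.
#'
#' Units with `z_i == 0` get `I_i = 0`; the neighbour axis of their label
#' follows the lag sign, the own axis defaults to "L" and the unit is
#' flagged in `tied`.
#'
#' @inheritParams global_moran
#' @param alpha Per-unit significance level (default 0.05).
#' @return A `lisa_result` with a data frame `table` (id, z, lag, Ii,
#'   quadrant, p_perm, significant) plus `alpha`, `n_perm`, `seed`.
#' @export
local_moran <- function(x, w, n_perm = 999L, seed = NULL, alpha = 0.05,
                        binary = FALSE) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- w$regions$n
  if (length(x) != n) stop("attribute length mismatch")
  if (anyNA(x)) stop("missing attribute values")
  if (stats::var(x) == 0) stop("degenerate input: attribute is constant")
  Wm <- weights_matrix(w, binary = binary)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- drop(Wm %*% z)
  Ii <- z * lag / m2

  own <- ifelse(z > 0, "H", "L")
  nbr <- ifelse(lag > 0, "H", "L")
  tied <- z == 0
  quadrant <- paste0(own, nbr)

  p_perm <- rep(NA_real_, n)
  if (n_perm > 0L) {
    if (is.null(seed)) stop("seed is required for permutation inference")
    set.seed(seed)
    for (i in seq_len(n)) {
      nb <- which(Wm[i, ] != 0)
      if (!length(nb)) next
      wi <- Wm[i, nb]
      pool <- z[-i]
      # n_perm draws of length(nb) values without replacement from pool
      draws <- matrix(0, n_perm, length(nb))
      for (b in seq_len(n_perm)) {
        draws[b, ] <- pool[sample.int(length(pool), length(nb))]
      }
      Ii_perm <- (z[i] / m2) * drop(draws %*% wi)
      p_perm[i] <- (1 + sum(abs(Ii_perm) >= abs(Ii[i]) - 1e-14)) /
        (n_perm + 1)
    }
  }

  tab <- data.frame(
    id = w$regions$ids, z = z, lag = lag, Ii = Ii,
    quadrant = quadrant, p_perm = p_perm,
    significant = !is.na(p_perm) & p_perm <= alpha,
    tied = tied, stringsAsFactors = FALSE
  )
  structure(list(table = tab, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "lisa_result")
}

#' @export
print.lisa_result <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  cat("<lisa_result> n =", nrow(x$table), " significant at",
      x$alpha, ":", nrow(sig), "\n")
  if (nrow(sig)) {
    for (q in c("HH", "LL", "HL", "LH")) {
      ids <- sig$id[sig$quadrant == q]
      if (length(ids)) cat(" ", q, ":", paste(ids, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Cluster classification table from a LISA result
#'
#' Returns the full per-unit table (no unit is ever dropped) and, as an
#' attribute, the conventional reporting view restricted to units
#' significant at `alpha`, grouped by cluster/outlier type.
#'
#' @param lisa A `lisa_result`.
#' @param alpha Significance level; defaults to the one stored in `lisa`.
#' @param p_adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (`"none"`, `"bonferroni"`, `"fdr"`, ...).
#' @return Data frame (id, Ii, quadrant, p, significant) with attribute
#'   `significant_view`: a data frame (quadrant, ids) listing significant
#'   units per type.
#' @export
classify_clusters <- function(lisa, alpha = NULL, p_adjust = "none") {
  stopifnot(inherits(lisa, "lisa_result"))
  if (is.null(alpha)) alpha <- lisa$alpha
  tab <- lisa$table
  p <- stats::p.adjust(tab$p_perm, method = p_adjust)
  out <- data.frame(id = tab$id, Ii = tab$Ii, quadrant = tab$quadrant,
                    p = p, significant = !is.na(p) & p <= alpha,
                    stringsAsFactors = FALSE)
  view <- do.call(rbind, lapply(c("HH", "LL", "HL", "LH"), function(q) {
    ids <- out$id[out$significant & out$quadrant == q]
    data.frame(quadrant = q,
               ids = paste(ids, collapse = ", "),
               n = length(ids), stringsAsFactors = FALSE)
  }))
  attr(out, "significant_view") <- view
  out
}
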
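#' Per-capita search index
#'
#' Converts a raw search-volume index (e.g. a daily-average Baidu index,
#' DBI) into its per-capita form (PBI) by dividing by year-end population.
#' Vectorized: `dbi` and `population` recycle like ordinary arithmetic, so a
#' whole panel column can be converted at once while keeping its unit-year
#' keys.
#'
#' @param dbi Non-negative index values.
#' @param population Positive year-end population counts.
#' @return `dbi / population`.
#' @export
dbi_to_pbi <- function(dbi, population) {
  if (anyNA(dbi) || anyNA(population)) {
    stop("missing dbi or population value")
  }
  if (any(population <= 0)) stop("population must be positive")
  if (any(dbi < 0)) stop("search index must be non-negative")
  dbi / population
}

#' Monthly shares of annual search volume
#'
#' @param counts 12 non-negative monthly totals (January..December).
#' @return Shares summing to 1.
#' @export
monthly_shares <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 12L) stop("need exactly 12 monthly values")
  if (anyNA(counts) || any(counts < 0)) {
    stop("monthly counts must be non-negative and complete")
  }
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero year: shares undefined")
  counts / tot
}

#' Seasonal concentration of monthly shares
#'
#' Measures how unevenly a year's search volume is spread over its 12
#' months. `R` is the Euclidean deviation of the monthly shares from the
#' uniform distribution, `R = sqrt(sum_i (r_i - 1/12)^2)`, and
#' `M = R / sqrt(11/12)` rescales it to `[0, 1]`: `M = 0` for a perfectly
#' uniform year and `M = 1` when all volume falls in a single month. Years
#' with `M` below `threshold` are labelled `"uniform"`.
#'
#' @param r 12 monthly shares summing to 1 (see [monthly_shares()]).
#' @param threshold Uniformity label cutoff, default 0.3.
#' @return A `concentration_result` list with `r`, `R`, `M`, `label`.
#' @export
concentration <- function(r, threshold = 0.3) {
  r <- as.numeric(r)
  if (length(r) != 12L) stop("need exactly 12 shares")
  if (abs(sum(r) - 1) > 1e-8) {
    stop("shares must sum to 1 (got ", format(sum(r)), ")")
  }
  if (any(r < -1e-12)) stop("shares must be non-negative")
  R <- sqrt(sum((r - 1 / 12)^2))
  M <- R / sqrt(11 / 12)
  structure(
    list(r = r, R = R, M = min(M, 1),
         label = if (M < threshold) "uniform" else "concentrated",
         threshold = threshold),
    class = "concentration_result"
  )
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("<concentration> R = %.4f  M = %.4f  (%s at %.2f)\n",
              x$R, x$M, x$label, x$threshold))
  invisible(x)
}

#' Annual temporal summary of a monthly index series
#'
#' Aggregates a long monthly table into one row per complete year: the mean
#' index, the seasonal concentration statistics `R` and `M`, the uniformity
#' label, and the top-3 peak months by share (calendar order breaks ties).
#' Years with missing months are dropped with a warning rather than
#' imputed.
#'
#' @param records Data frame with columns `year`, `month` (1..12), `dbi`.
#' @param threshold Uniformity cutoff passed to [concentration()].
#' @return Data frame with one row per complete year: `year`, `mean_dbi`,
#'   `R`, `M`, `label`, `peak_months` (comma-separated month numbers).
#' @export
annual_summary <- function(records, threshold = 0.3) {
  stopifnot(all(c("year", "month", "dbi") %in% names(records)))
  years <- sort(unique(records$year))
  rows <- list()
  for (y in years) {
    sub <- records[records$year == y, ]
    agg <- tapply(sub$dbi, factor(sub$month, levels = 1:12), sum)
    if (anyNA(agg)) {
      warning("year ", y, " has missing months; excluded from summary")
      next
    }
    conc <- concentration(monthly_shares(agg), threshold)
    # peak months: largest shares, ties broken by calendar order
    ord <- order(-conc$r, seq_len(12L))
    rows[[length(rows) + 1L]] <- data.frame(
      year = y,
      mean_dbi = mean(sub$dbi),
      R = conc$R,
      M = conc$M,
      label = conc$label,
      peak_months = paste(sort(ord[1:3]), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(year = integer(0), mean_dbi = numeric(0),
                      R = numeric(0), M = numeric(0), label = character(0),
                      peak_months = character(0)))
  }
  do.call(rbind, rows)
}
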
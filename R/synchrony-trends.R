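# Consumer-resource mismatch series, linear trends, and case-bootstrap
# percentile confidence intervals.
#
# Mismatch is signed as hatch median minus resource median: positive values
# mean the consumer's median hatch date fell after the resource's 50% date.
# Trends are ordinary least squares of mismatch on calendar year, with the
# year axis centered on the first study year so the intercept reads as the
# mismatch at the start of the series. Uncertainty comes from a
# non-parametric case bootstrap that resamples whole (year, mismatch) pairs
# with replacement; confidence intervals are percentile (quantile) intervals
# with quantiles interpolated between order statistics (R quantile type 7).

#' Mismatch series between hatch and resource phenology
#'
#' @param hatch_medians data.frame (year, hatch_median_doy).
#' @param phenology Phenology table (year, currency, median_doy, defined)
#'   from [phenology_estimates()].
#' @param currency Which resource currency to difference against.
#' @return data.frame (year, currency, mismatch_days) over the years present
#'   in both inputs and with defined resource phenology;
#'   mismatch = hatch median - resource median.
#' @export
mismatch_series <- function(hatch_medians, phenology,
                            currency = c("abundance", "biomass")) {
  currency <- match.arg(currency)
  .check_columns(hatch_medians, c("year", "hatch_median_doy"), "hatch medians")
  .check_columns(phenology, c("year", "currency", "median_doy"), "phenology table")
  res <- phenology[phenology$currency == currency, , drop = FALSE]
  if ("defined" %in% names(res)) res <- res[res$defined, , drop = FALSE]
  m <- match(hatch_medians$year, res$year)
  keep <- !is.na(m)
  if (!any(keep)) stop("no overlapping years between hatch and resource series")
  out <- data.frame(year = hatch_medians$year[keep], currency = currency,
                    mismatch_days = hatch_medians$hatch_median_doy[keep] -
                      res$median_doy[m[keep]],
                    stringsAsFactors = FALSE)
  out[order(out$year), , drop = FALSE]
}

#' Yearly median hatch dates from nest records
#'
#' @param nests data.frame (year, hatch_doy).
#' @return data.frame (year, hatch_median_doy, n_nests).
#' @export
hatch_medians <- function(nests) {
  .check_columns(nests, c("year", "hatch_doy"), "nest table")
  yrs <- sort(unique(nests$year))
  data.frame(year = yrs,
             hatch_median_doy = vapply(yrs, function(y) {
               stats::median(nests$hatch_doy[nests$year == y])
             }, numeric(1L)),
             n_nests = vapply(yrs, function(y) sum(nests$year == y), integer(1L)))
}

#' Ordinary least-squares time trend
#'
#' Closed-form OLS of mismatch on year, with year centered on the first
#' (smallest) year so the intercept is the fitted mismatch at series start.
#'
#' @param year Calendar years (>= 3 values, >= 2 distinct).
#' @param mismatch_days Mismatch values.
#' @return Named numeric vector `c(slope, intercept)` (days/yr, days).
#' @export
ols_trend <- function(year, mismatch_days) {
  stopifnot(length(year) == length(mismatch_days))
  if (length(year) < 3L) stop("need at least 3 years")
  if (length(unique(year)) < 2L) stop("year values are constant")
  x <- year - min(year)
  xb <- mean(x); yb <- mean(mismatch_days)
  slope <- sum((x - xb) * (mismatch_days - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}

#' Case-bootstrap percentile confidence interval
#'
#' Resamples whole observations with replacement (n per replicate equal to
#' n observed) and returns the percentile interval of the replicated
#' statistic. When the full resample space is no larger than `n_boot`
#' (n^n <= n_boot) all resamples are enumerated with equal weight, making
#' the interval exact and deterministic; otherwise `n_boot` Monte-Carlo
#' replicates are drawn under `seed`. Replicates where the statistic is
#' undefined (`NA`/`NaN`, e.g. a slope on a resample of one repeated year)
#' are discarded and counted; more than 50% discarded is an error.
#'
#' @param data Vector, matrix or data.frame of observations (rows resampled).
#' @param statistic Function of the resampled data returning a numeric
#'   scalar or fixed-length named vector.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for the Monte-Carlo path.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `ci` (matrix: one row per statistic component, columns
#'   lower/upper), `n_replicates`, `n_discarded`, `exact` flag, and the
#'   replicate `statistics` matrix.
#' @export
case_bootstrap <- function(data, statistic, n_boot = 10000L, seed = NULL,
                           conf_level = 0.95) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 3L) stop("need at least 3 observations")
  take <- if (is.null(dim(data))) {
    function(idx) data[idx]
  } else {
    function(idx) data[idx, , drop = FALSE]
  }
  eval_stat <- function(idx) {
    out <- tryCatch(statistic(take(idx)), error = function(e) NA_real_)
    as.numeric(out)
  }

  exact <- n^n <= n_boot
  if (exact) {
    idx_mat <- as.matrix(expand.grid(rep(list(seq_len(n)), n),
                                     KEEP.OUT.ATTRS = FALSE))
  } else {
    if (!is.null(seed)) set.seed(derive_seeds(seed, 1L))
    idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE),
                      nrow = n_boot, ncol = n)
  }
  # probe on the identity resample (always well defined) to size the output
  first <- statistic(take(seq_len(n)))
  p <- length(first)
  stats_mat <- matrix(NA_real_, nrow = nrow(idx_mat), ncol = p)
  for (b in seq_len(nrow(idx_mat))) {
    val <- eval_stat(idx_mat[b, ])
    if (length(val) == p) stats_mat[b, ] <- val
  }
  ok <- stats::complete.cases(stats_mat)
  n_discarded <- sum(!ok)
  if (n_discarded > 0.5 * nrow(stats_mat)) {
    stop("more than 50% of bootstrap replicates were degenerate")
  }
  alpha <- (1 - conf_level) / 2
  ci <- t(apply(stats_mat[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), type = 7, names = FALSE))
  dimnames(ci) <- list(names(first) %||% paste0("stat", seq_len(p)),
                       c("lower", "upper"))
  list(ci = ci, n_replicates = sum(ok), n_discarded = n_discarded,
       exact = exact, statistics = stats_mat[ok, , drop = FALSE])
}

#' Linear mismatch trend with case-bootstrap confidence intervals
#'
#' Point estimates (OLS slope and intercept, mean mismatch) plus 95%
#' percentile intervals from case-resampling years.
#'
#' @param series Mismatch series from [mismatch_series()].
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return Object of class `trend_fit`: list with `slope`, `intercept`,
#'   `mean_mismatch`, `ci` (matrix), `n_years`, `n_boot`, `n_discarded`,
#'   `exact`, `seed`, `currency`.
#' @export
trend_with_ci <- function(series, n_boot = 10000L, seed = NULL,
                          conf_level = 0.95) {
  .check_columns(series, c("year", "mismatch_days"), "mismatch series")
  est <- ols_trend(series$year, series$mismatch_days)
  stat <- function(d) {
    tr <- ols_trend(d[, 1L], d[, 2L])
    c(slope = tr[["slope"]], intercept = tr[["intercept"]],
      mean_mismatch = mean(d[, 2L]))
  }
  dat <- cbind(series$year, series$mismatch_days)
  bs <- case_bootstrap(dat, stat, n_boot = n_boot, seed = seed,
                       conf_level = conf_level)
  structure(list(slope = est[["slope"]], intercept = est[["intercept"]],
                 mean_mismatch = mean(series$mismatch_days),
                 ci = bs$ci, n_years = nrow(series), n_boot = n_boot,
                 n_discarded = bs$n_discarded, exact = bs$exact,
                 seed = seed,
                 currency = if ("currency" %in% names(series))
                   series$currency[1L] else NA_character_),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Mismatch trend (", x$currency, "), n = ", x$n_years, " years\n", sep = "")
  cat(sprintf("  slope:         %6.3f d/yr  [%.3f, %.3f]\n",
              x$slope, x$ci["slope", 1L], x$ci["slope", 2L]))
  cat(sprintf("  intercept:     %6.3f d     [%.3f, %.3f]\n",
              x$intercept, x$ci["intercept", 1L], x$ci["intercept", 2L]))
  cat(sprintf("  mean mismatch: %6.3f d     [%.3f, %.3f]\n",
              x$mean_mismatch, x$ci["mean_mismatch", 1L],
              x$ci["mean_mismatch", 2L]))
  cat("  bootstrap: ", if (x$exact) "exact enumeration" else
    paste0(x$n_boot, " replicates"),
    ", ", x$n_discarded, " degenerate replicate(s) discarded\n", sep = "")
  invisible(x)
}
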
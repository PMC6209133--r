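#' Weighted median
#'
#' The smallest value whose cumulative weight reaches 50% of the total
#' weight (ties broken toward the lower value). With equal weights this
#' equals the lower ordinary median.
#'
#' @param x Numeric values.
#' @param w Nonnegative weights.
#' @return The weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= 0.5 * sum(w))[1]]
}

#' Loess-smooth noisy validation series
#'
#' Smooths a hazard series over calendar year with local linear regression
#' (tricube weights, degree 1, no robustness iterations), span 0.85, the
#' convention used to de-noise direct tabulations before computing
#' validity metrics. Series with fewer than 4 points are returned
#' unsmoothed and flagged.
#'
#' @param series A `data.table`/`data.frame` with at least `year` and a
#'   value column.
#' @param span Loess span (fraction of points in each local fit).
#' @param value Name of the value column.
#' @param by Character vector of columns defining separate series (e.g.
#'   `c("country", "bin_label")`); `NULL` for a single series.
#' @return A `data.table`: the input plus columns `smoothed` (fitted
#'   values) and `smooth_ok` (`FALSE` where too few points).
#' @export
loess_smooth <- function(series, span = 0.85, value = "q", by = NULL) {
  dt <- data.table::as.data.table(series)
  assert_cols(dt, c("year", value, by), "series")
  smooth_one <- function(sd) {
    yv <- sd[[value]]
    ok <- sum(!is.na(yv)) >= 4
    if (!ok) return(list(smoothed = yv, smooth_ok = FALSE))
    fit <- stats::loess(stats::as.formula(paste(value, "~ year")), data = sd,
                        span = span, degree = 1, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    list(smoothed = stats::predict(fit, newdata = sd), smooth_ok = TRUE)
  }
  if (is.null(by)) {
    dt[, c("smoothed", "smooth_ok") := smooth_one(.SD)]
  } else {
    dt[, c("smoothed", "smooth_ok") := smooth_one(.SD), by = by]
  }
  dt[]
}

#' Pair indirect estimates with direct validation tabulations
#'
#' Inner-joins an indirect trend table with a direct tabulation on (group,
#' year, bin) after applying the standard comparison filters: keep years at
#' or after `min_year` and within `max_recall` years of each source's
#' survey (applied to each table that carries a `survey_year` column).
#'
#' @param indirect `data.table` of indirect estimates with columns `year`,
#'   `bin_label`, `q` (and optionally `survey_year`).
#' @param direct `data.table` of direct estimates with columns `year`,
#'   `bin_label`, `q`, and `n` (entrants; used as metric weights), and
#'   optionally `survey_year`.
#' @param group Character vector of join group columns (e.g. `"country"`).
#' @param max_recall Maximum years between a source's survey and the
#'   estimate year.
#' @param min_year Earliest estimate year kept.
#' @return A `data.table` with columns `group..., year, bin_label,
#'   estimate, validation, weight`.
#' @export
pair_concurrent_estimates <- function(indirect, direct, group = "country",
                                      max_recall = 15, min_year = 1990) {
  ind <- data.table::as.data.table(indirect)
  dir <- data.table::as.data.table(direct)
  assert_cols(ind, c(group, "year", "bin_label", "q"), "indirect estimates")
  assert_cols(dir, c(group, "year", "bin_label", "q", "n"),
              "direct estimates")
  recall_filter <- function(dt) {
    dt <- dt[year >= min_year]
    if ("survey_year" %in% names(dt)) {
      dt <- dt[survey_year - year <= max_recall]
    }
    dt
  }
  ind <- recall_filter(ind)
  dir <- recall_filter(dir)
  keys <- c(group, "year", "bin_label")
  out <- merge(ind[, c(keys, "q"), with = FALSE],
               dir[, c(keys, "q", "n"), with = FALSE],
               by = keys, suffixes = c("_est", "_val"))
  if (nrow(out) == 0) warning("pair_concurrent_estimates: empty intersection")
  data.table::setnames(out, c("q_est", "q_val", "n"),
                       c("estimate", "validation", "weight"))
  data.table::setorderv(out, keys)
  out[]
}

#' Predictive-validity metric suite
#'
#' Computes the five standard out-of-sample metrics on paired
#' estimate/validation series, each weighted by the validation sample sizes
#' (children entering the bin): mean error (ME, systematic bias), standard
#' deviation of the errors (SDE, weighted consistently with the other
#' metrics), median relative error (MRE, estimate / validation; 1 = no
#' bias), median absolute percentage error (MAPE, `100 |error| /
#' validation`), and the coefficient of determination
#' `R^2 = 1 - sum w e^2 / sum w (q - qbar_w)^2`. Cells with zero validation
#' values are excluded from the relative metrics (MRE, MAPE) and counted.
#'
#' @param paired Output of [pair_concurrent_estimates()] (columns
#'   `estimate`, `validation`, `weight`).
#' @param by Optional character vector: compute the metrics separately per
#'   group (e.g. `"bin_label"`); `NULL` for one overall row.
#' @return A `data.table` with columns `me, sde, mre, mape, r2,
#'   n_pairs, n_zero_validation` (plus the `by` columns).
#' @export
compute_metrics <- function(paired, by = NULL) {
  dt <- data.table::as.data.table(paired)
  assert_cols(dt, c("estimate", "validation", "weight", by),
              "paired series")
  one <- function(sd) {
    w <- sd$weight
    if (sum(w) <= 0) stop("compute_metrics: all-zero weights")
    e <- sd$estimate - sd$validation
    me <- sum(w * e) / sum(w)
    sde <- sqrt(sum(w * (e - me)^2) / sum(w))
    pos <- sd$validation > 0
    mre <- weighted_median(sd$estimate[pos] / sd$validation[pos], w[pos])
    mape <- weighted_median(100 * abs(e[pos]) / sd$validation[pos], w[pos])
    qbar <- sum(w * sd$validation) / sum(w)
    r2 <- 1 - sum(w * e^2) / sum(w * (sd$validation - qbar)^2)
    list(me = me, sde = sde, mre = mre, mape = mape, r2 = r2,
         n_pairs = nrow(sd), n_zero_validation = sum(!pos))
  }
  if (is.null(by)) dt[, one(.SD)] else dt[, one(.SD), by = by]
}
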
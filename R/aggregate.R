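#' Survival to bin entry
#'
#' Given a vector of per-bin discrete hazards `q`, returns the probability
#' of surviving to the *entry* of each bin: `S(1) = 1` and
#' `S(a) = prod_{alpha < a} (1 - q_alpha)`. Under this convention the
#' expected-entering-bin weight of the first bin is the full birth weight.
#'
#' @param q Numeric vector of hazards in `[0, 1]`, ordered by bin.
#' @return Numeric vector of the same length.
#' @examples
#' survival_to_entry(c(0.1, 0.1, 0.1)) # 1, 0.9, 0.81
#' @export
survival_to_entry <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  if (!length(q)) return(numeric(0))
  c(1, cumprod(1 - q))[seq_along(q)]
}

# Matrix version: q is (A x n) with bins in rows; survival to entry per
# column by row-recursive products (vectorized across columns, and exact
# at the q = 1 boundary).
survival_to_entry_mat <- function(qmat) {
  A <- nrow(qmat)
  S <- matrix(1, A, ncol(qmat))
  for (a in seq_len(A - 1)) {
    S[a + 1, ] <- S[a, ] * (1 - qmat[a, ])
  }
  S
}

#' Expected children entering each age bin (EEB)
#'
#' For every (hypothetical child, bin) row, computes
#' `EEB = POB * CEB * S` where `S` is the child's predicted survival to the
#' entry of the bin and `CEB` is the mother's children ever born at the
#' survey. When draws are present, per-draw EEB is computed from per-draw
#' hazards.
#'
#' @param hyp Hypothetical-child table from
#'   [enumerate_hypothetical_children()].
#' @param pred A `hazard_prediction` for the rows `hyp` crossed with all
#'   bins, ordered bin-fastest within child (the layout produced by
#'   [hypothetical_prediction_rows()]).
#' @param scheme The [age_bin_scheme()].
#' @return A list with `eeb`: a `data.table` of (child, bin) rows carrying
#'   `q`, `S`, `eeb`; and, when draws are present, matrices `q_draws` and
#'   `eeb_draws` aligned with the rows.
#' @export
compute_eeb <- function(hyp, pred, scheme = age_bin_scheme()) {
  A <- n_bins(scheme)
  n_child <- nrow(hyp)
  stopifnot(length(pred$point) == n_child * A)
  qm <- matrix(pred$point, nrow = A)  # bin-fastest layout
  Sm <- survival_to_entry_mat(qm)
  base_w <- rep(hyp$pob * hyp$ceb, each = A)
  out <- hyp[rep(seq_len(n_child), each = A)]
  out[, "bin_index" := rep(seq_len(A), n_child)]
  out[, "bin_label" := scheme$label[bin_index]]
  out[, "q" := as.vector(qm)]
  out[, "S" := as.vector(Sm)]
  out[, "eeb" := base_w * as.vector(Sm)]
  res <- list(eeb = out[])
  if (!is.null(pred$draws)) {
    nd <- ncol(pred$draws)
    q_draws <- pred$draws
    eeb_draws <- matrix(0, nrow(q_draws), nd)
    for (j in seq_len(nd)) {
      Sj <- survival_to_entry_mat(matrix(q_draws[, j], nrow = A))
      eeb_draws[, j] <- base_w * as.vector(Sj)
    }
    res$q_draws <- q_draws
    res$eeb_draws <- eeb_draws
  }
  res
}

# Reshape a cells x draws matrix of aggregated hazards into the long
# (cell, draw, q) table carried on aggregated_trend objects.
draws_to_long <- function(est, qd, grouping) {
  id_cols <- c(grouping, "year", "bin_index", "bin_label")
  wide <- cbind(est[, id_cols, with = FALSE],
                data.table::as.data.table(qd))
  long <- data.table::melt(wide, id.vars = id_cols, variable.name = "draw",
                           value.name = "q", variable.factor = TRUE)
  long[, "draw" := as.integer(draw)]
  data.table::setorderv(long, c(id_cols, "draw"))
  long[]
}

#' Aggregate per-child hazards into population trends
#'
#' Forms the EEB-weighted mean hazard per (group, birth year, bin):
#' `q_hat = sum_m q * EEB / sum_m EEB`, whose numerator is the expected
#' number of deaths and denominator the expected number of children
#' entering the bin. Survey weights, when enabled, multiply both summands.
#' When per-draw hazards are supplied the aggregation is repeated per draw
#' and summarised by 2.5% / 97.5% empirical quantiles, with the point
#' estimate taken as the mean of the draws.
#'
#' @param eeb Result of [compute_eeb()] (list), or its `$eeb` table when no
#'   draws are in play.
#' @param grouping Character vector of grouping columns (e.g. `"country"`).
#' @param use_survey_weights Multiply `survey_weight` into the summands.
#' @return An object of class `aggregated_trend`: list with `estimates` (a
#'   `data.table` with `q`, `q_plugin`, `lwr`, `upr`, `expected_deaths`,
#'   `expected_entrants` per (group, year, bin)) and `draws` (long
#'   `data.table` of per-draw aggregated hazards, or `NULL`).
#' @export
aggregate_trends <- function(eeb, grouping = "country",
                             use_survey_weights = TRUE) {
  if (data.table::is.data.table(eeb) || is.data.frame(eeb)) {
    eeb <- list(eeb = data.table::as.data.table(eeb))
  }
  tab <- data.table::as.data.table(eeb$eeb)
  assert_cols(tab, c(grouping, "birth_year", "bin_index", "bin_label", "q",
                     "eeb"), "EEB table")
  sw <- if (use_survey_weights && "survey_weight" %in% names(tab)) {
    tab$survey_weight
  } else rep(1, nrow(tab))

  cell <- tab[, c(grouping, "birth_year", "bin_index", "bin_label"),
              with = FALSE]
  data.table::setnames(cell, "birth_year", "year")
  cell_id <- do.call(paste, c(cell, sep = "\r"))
  cf <- factor(cell_id, levels = unique(cell_id))

  num <- rowsum(tab$q * tab$eeb * sw, cf, reorder = FALSE)[, 1]
  den <- rowsum(tab$eeb * sw, cf, reorder = FALSE)[, 1]
  est <- cell[!duplicated(cell_id)]
  est[, "expected_deaths" := num]
  est[, "expected_entrants" := den]
  est[, "q_plugin" := data.table::fifelse(den > 0, num / den, NA_real_)]
  if (any(den == 0)) {
    message(sprintf("aggregate_trends: %d cell(s) with zero expected entrants; estimate undefined",
                    sum(den == 0)))
  }

  draws_long <- NULL
  if (!is.null(eeb$q_draws)) {
    numd <- rowsum(eeb$q_draws * eeb$eeb_draws * sw, cf, reorder = FALSE)
    dend <- rowsum(eeb$eeb_draws * sw, cf, reorder = FALSE)
    qd <- numd / dend
    est[, "q" := rowMeans(qd, na.rm = TRUE)]
    est[, "lwr" := apply(qd, 1, q_lower)]
    est[, "upr" := apply(qd, 1, q_upper)]
    est[, "n_draws" := ncol(qd)]
    draws_long <- draws_to_long(est, qd, grouping)
  } else {
    est[, "q" := q_plugin]
    est[, c("lwr", "upr") := NA_real_]
    est[, "n_draws" := 0L]
  }
  data.table::setorderv(est, c(grouping, "year", "bin_index"))
  if (!is.null(draws_long)) {
    data.table::setorderv(draws_long, c(grouping, "year", "bin_index", "draw"))
  }
  structure(list(estimates = est[], draws = draws_long, grouping = grouping),
            class = "aggregated_trend")
}

#' @export
print.aggregated_trend <- function(x, ...) {
  cat(sprintf("Aggregated mortality trend: %d (group, year, bin) cells%s\n",
              nrow(x$estimates),
              if (is.null(x$draws)) "" else
                sprintf(", %d uncertainty draws", x$estimates$n_draws[1])))
  print(utils::head(x$estimates, 10))
  invisible(x)
}

#' Combine age bins into cumulative mortality probabilities
#'
#' Combines contiguous-from-birth age bins as independent conditional
#' probabilities: `q_combined = 1 - prod_a (1 - q_a)`. The standard targets
#' are `"1q0"` (bins up to age 1) and `"5q0"` (all under-five bins). With
#' draws present, combination is applied per draw and then summarised; the
#' point estimate is the mean of the combined draws.
#'
#' @param trend An `aggregated_trend`.
#' @param target `"5q0"`, `"1q0"`, or an integer vector of bin indices that
#'   must be contiguous and start at bin 1.
#' @param scheme The [age_bin_scheme()] (used to resolve named targets).
#' @return A `data.table` per (group, year) with `q`, `lwr`, `upr`.
#' @export
combine_bins <- function(trend, target = "5q0", scheme = age_bin_scheme()) {
  stopifnot(inherits(trend, "aggregated_trend"))
  bins <- resolve_target_bins(target, scheme)
  grouping <- trend$grouping
  lab <- if (is.character(target)) target else
    sprintf("bins1-%d", max(bins))

  # Within a cell, missing later-bin hazards are tolerated when an earlier
  # bin already reaches 1 (no entrants survive to the undefined bins).
  combine_dt <- function(dt, qcol) {
    byc <- c(grouping, "year", intersect("draw", names(dt)))
    dt[bin_index %in% bins, {
      qv <- get(qcol)
      ok <- !is.na(qv)
      list(n_bins = if (any(qv[ok] >= 1)) length(bins) else sum(ok),
           q = 1 - prod(1 - qv[ok]))
    }, by = byc]
  }
  if (!is.null(trend$draws)) {
    per_draw <- combine_dt(trend$draws, "q")
    per_draw <- per_draw[n_bins == length(bins)]
    out <- per_draw[, list(q = mean(q), lwr = q_lower(q), upr = q_upper(q)),
                    by = c(grouping, "year")]
  } else {
    out <- combine_dt(trend$estimates, "q")
    out <- out[n_bins == length(bins)]
    out[, "n_bins" := NULL]
    out[, c("lwr", "upr") := NA_real_]
  }
  out[, "target" := lab]
  data.table::setorderv(out, c(grouping, "year"))
  out[]
}

resolve_target_bins <- function(target, scheme) {
  if (is.character(target)) {
    target <- match.arg(target, c("5q0", "1q0"))
    bins <- if (target == "5q0") seq_len(n_bins(scheme)) else
      which(scheme$end <= 365)
  } else {
    bins <- sort(as.integer(target))
  }
  if (bins[1] != 1L || !all(diff(bins) == 1L)) {
    stop("combined bins must be contiguous and start from birth (bin 1)")
  }
  bins
}

#' Summarize a set of draws into a point estimate and quantile bounds
#'
#' Point = mean of draws; bounds = empirical 2.5% and 97.5% quantiles using
#' the linear-interpolation (type 7) convention.
#'
#' @param draws Numeric vector (one cell) or matrix (cells in rows, draws in
#'   columns) of at least 2 draws.
#' @return A `data.table` with columns `q`, `lwr`, `upr`.
#' @export
summarize_uncertainty <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  stopifnot(ncol(draws) >= 2)
  data.table::data.table(q = rowMeans(draws),
                         lwr = apply(draws, 1, q_lower),
                         upr = apply(draws, 1, q_upper))
}
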
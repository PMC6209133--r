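#' Build prediction rows for hypothetical children
#'
#' Crosses a hypothetical-child table with all age bins of the scheme, in
#' the bin-fastest-within-child layout that [compute_eeb()] expects.
#'
#' @param hyp Table from [enumerate_hypothetical_children()].
#' @param scheme The [age_bin_scheme()].
#' @return A `data.table` with one row per (hypothetical child, bin).
#' @export
hypothetical_prediction_rows <- function(hyp, scheme = age_bin_scheme()) {
  A <- n_bins(scheme)
  rows <- hyp[rep(seq_len(nrow(hyp)), each = A)]
  rows[, "bin_index" := rep(seq_len(A), nrow(hyp))]
  rows[]
}

#' Indirect estimation of age-specific mortality trends from SBH data
#'
#' The end-to-end indirect pipeline: enumerate the hypothetical children of
#' every SBH mother, predict their per-bin hazards from a trained
#' discrete-time survival model, weight by probability-of-birth and
#' survival (EEB), and aggregate to population trends per (group, year,
#' bin). Mothers are processed in chunks so memory stays bounded at scale;
#' parameter draws are taken once and shared across chunks, so results do
#' not depend on the chunking for a fixed `chunk_mothers`.
#'
#' @param fit A `dtsa_fit` from [fit_full()].
#' @param sbh SBH mother table ([read_mothers()] layout).
#' @param sdi_table Country-year SDI table.
#' @param pob_table A [tabulate_pob()] table.
#' @param grouping Character vector of mother columns to aggregate by.
#' @param n_draws Number of parameter draws for uncertainty (0 = point
#'   estimates only).
#' @param seed Integer seed for the draws.
#' @param use_survey_weights Multiply survey weights into the aggregation
#'   summands.
#' @param min_mother_age Youngest possible age at birth (years).
#' @param chunk_mothers Upper bound on mothers per prediction chunk; with
#'   draws in play the effective chunk shrinks so the per-chunk draw
#'   matrices stay within a fixed memory budget.
#' @param quiet Suppress progress messages.
#' @return An `aggregated_trend` (see [aggregate_trends()]).
#' @export
estimate_trends <- function(fit, sbh, sdi_table, pob_table,
                            grouping = "country", n_draws = 0, seed = NULL,
                            use_survey_weights = TRUE, min_mother_age = 12,
                            chunk_mothers = 4000, quiet = TRUE) {
  stopifnot(inherits(fit, "dtsa_fit"))
  mo <- clean_mothers(sbh, quiet = quiet)
  mo <- mo[ceb > 0]
  if (nrow(mo) == 0) stop("no SBH mothers with ceb > 0")
  A <- n_bins(fit$scheme)

  draws <- NULL
  if (n_draws > 0) {
    new_surveys <- setdiff(unique(as.character(mo$survey_id)),
                           fit$survey_levels)
    new_countries <- setdiff(unique(as.character(mo$country)),
                             fit$country_levels)
    new_cb <- as.vector(outer(new_countries, fit$scheme$label, paste,
                              sep = "\r"))
    draws <- prepare_draws(fit, n_draws, new_surveys, new_cb, seed = seed)
  }

  if (n_draws > 0) {
    # keep each (rows x draws) matrix near 2e7 elements (~160 MB of doubles
    # across the handful of live copies); ~25 hypothetical children x A
    # bins per mother
    chunk_mothers <- max(100L, min(chunk_mothers,
                                   floor(2e7 / n_draws / (25 * A))))
  }
  chunks <- split(seq_len(nrow(mo)),
                  ceiling(seq_len(nrow(mo)) / chunk_mothers))
  acc <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    hyp <- enumerate_hypothetical_children(mo[chunks[[ci]]], sdi_table,
                                           pob_table,
                                           min_mother_age = min_mother_age,
                                           quiet = TRUE)
    rows <- hypothetical_prediction_rows(hyp, fit$scheme)
    pred <- predict_hazard(fit, rows, n_draws = n_draws, draws = draws)
    eeb <- compute_eeb(hyp, pred, fit$scheme)
    sw <- if (use_survey_weights) eeb$eeb$survey_weight else
      rep(1, nrow(eeb$eeb))
    cell <- eeb$eeb[, c(grouping, "birth_year", "bin_index", "bin_label"),
                    with = FALSE]
    cid <- do.call(paste, c(cell, sep = "\r"))
    cf <- factor(cid, levels = unique(cid))
    part <- cell[!duplicated(cid)]
    part[, "num" := rowsum(eeb$eeb$q * eeb$eeb$eeb * sw, cf,
                           reorder = FALSE)[, 1]]
    part[, "den" := rowsum(eeb$eeb$eeb * sw, cf, reorder = FALSE)[, 1]]
    if (!is.null(draws)) {
      numd <- rowsum(eeb$q_draws * eeb$eeb_draws * sw, cf, reorder = FALSE)
      dend <- rowsum(eeb$eeb_draws * sw, cf, reorder = FALSE)
      colnames(numd) <- paste0("num_d", seq_len(n_draws))
      colnames(dend) <- paste0("den_d", seq_len(n_draws))
      part <- cbind(part, numd, dend)
    }
    acc[[ci]] <- part
    if (!quiet) message(sprintf("estimate_trends: chunk %d/%d done",
                                ci, length(chunks)))
  }
  all_parts <- data.table::rbindlist(acc)
  sum_cols <- setdiff(names(all_parts),
                      c(grouping, "birth_year", "bin_index", "bin_label"))
  tot <- all_parts[, lapply(.SD, sum), .SDcols = sum_cols,
                   by = c(grouping, "birth_year", "bin_index", "bin_label")]

  est <- tot[, c(grouping, "birth_year", "bin_index", "bin_label"),
             with = FALSE]
  data.table::setnames(est, "birth_year", "year")
  est[, "expected_deaths" := tot$num]
  est[, "expected_entrants" := tot$den]
  est[, "q_plugin" := data.table::fifelse(tot$den > 0, tot$num / tot$den,
                                          NA_real_)]
  draws_long <- NULL
  if (!is.null(draws)) {
    numd <- as.matrix(tot[, paste0("num_d", seq_len(n_draws)), with = FALSE])
    dend <- as.matrix(tot[, paste0("den_d", seq_len(n_draws)), with = FALSE])
    qd <- numd / dend
    est[, "q" := rowMeans(qd, na.rm = TRUE)]
    est[, "lwr" := apply(qd, 1, q_lower)]
    est[, "upr" := apply(qd, 1, q_upper)]
    est[, "n_draws" := n_draws]
    draws_long <- draws_to_long(est, qd, grouping)
  } else {
    est[, "q" := q_plugin]
    est[, c("lwr", "upr") := NA_real_]
    est[, "n_draws" := 0L]
  }
  data.table::setorderv(est, c(grouping, "year", "bin_index"))
  structure(list(estimates = est[], draws = draws_long, grouping = grouping),
            class = "aggregated_trend")
}

#' Write an aggregated trend as delimited text
#'
#' One row per (group, year, bin) with the hazard estimate, uncertainty
#' bounds, expected deaths and expected entrants.
#'
#' @param trend An `aggregated_trend`.
#' @param path Output file path.
#' @export
write_trend <- function(trend, path) {
  stopifnot(inherits(trend, "aggregated_trend"))
  data.table::fwrite(trend$estimates, path)
  invisible(path)
}
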
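#' Enumerate the hypothetical children of SBH mothers
#'
#' For each mother in a summary birth history, enumerates one hypothetical
#' child per calendar year from the survey year back to the year she was
#' `min_mother_age`, and attaches the covariates needed for hazard
#' prediction: mother's age at the birth, SDI of her country in the birth
#' year, her survey-time `cd / ceb` ratio, an imputed CEB at birth
#' ([impute_ceb_at_birth()]), and the probability that the birth actually
#' happened ([lookup_pob()]).
#'
#' Mothers with `ceb = 0` carry zero POB-CEB weight in aggregation, so they
#' are excluded by default; set `include_childless = TRUE` to enumerate them
#' anyway (with zero weight).
#'
#' @param mothers SBH mother table (see [read_mothers()]).
#' @param sdi_table Country-year SDI table; years without SDI are skipped
#'   with a logged count (attribute `"n_skipped_sdi"`).
#' @param pob_table A [tabulate_pob()] table.
#' @param min_mother_age Youngest age at which a birth is considered
#'   possible (years).
#' @param include_childless Enumerate mothers with `ceb = 0`.
#' @param quiet Suppress messages.
#' @return A `data.table`, one row per (mother, hypothetical birth year),
#'   with columns `mother_id, survey_id, country, region, survey_year,
#'   survey_weight, ceb, cd, cd_over_ceb, t, birth_year,
#'   mother_age_at_birth, ceb_at_birth, sdi, pob` (plus `admin1_area` when
#'   present).
#' @export
enumerate_hypothetical_children <- function(mothers, sdi_table, pob_table,
                                            min_mother_age = 12,
                                            include_childless = FALSE,
                                            quiet = FALSE) {
  mo <- clean_mothers(mothers, quiet = quiet)
  if (!include_childless) mo <- mo[ceb > 0]
  if (nrow(mo) == 0) stop("no mothers to enumerate")
  mo[, "age_at_survey" := as.integer(age_at_survey)]
  n_t <- pmax(mo$age_at_survey - min_mother_age, 0L) + 1L

  # carry every mother attribute through (arbitrary grouping keys included),
  # except columns recomputed per hypothetical child
  keep <- setdiff(names(mo), c("t", "birth_year", "mother_age_at_birth",
                               "ceb_at_birth", "pob", "sdi", "cd_over_ceb"))
  hyp <- mo[rep(seq_len(nrow(mo)), n_t), keep, with = FALSE]
  hyp[, "t" := sequence(n_t) - 1L]
  hyp[, "birth_year" := survey_year - t]
  hyp[, "mother_age_at_birth" := age_at_survey - t]
  hyp[, "cd_over_ceb" := ifelse(ceb > 0, cd / ceb, 0)]
  hyp[, "pob" := lookup_pob(pob_table, region, age_at_survey, ceb, t)]
  hyp[, "ceb_at_birth" := impute_ceb_at_birth(pob_table, .SD, birth_year)]

  sdi <- data.table::as.data.table(sdi_table)
  assert_cols(sdi, c("country", "year", "sdi"), "SDI table")
  hyp <- merge(hyp, sdi[, list(country, birth_year = year, sdi)],
               by = c("country", "birth_year"), all.x = TRUE, sort = FALSE)
  n_skip <- sum(is.na(hyp$sdi))
  if (n_skip > 0) {
    if (!quiet) {
      message(sprintf(
        "enumerate_hypothetical_children: skipped %d mother-year(s) with missing SDI",
        n_skip))
    }
    hyp <- hyp[!is.na(sdi)]
  }
  data.table::setorder(hyp, mother_id, t)
  data.table::setattr(hyp, "n_skipped_sdi", n_skip)
  hyp[]
}
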
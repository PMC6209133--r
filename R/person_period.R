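#' Reshape birth histories into person-period form
#'
#' Expands each child of a complete birth history into one row per age bin
#' entered, the standard reshape for discrete-time survival analysis. A child
#' who died in bin *k* contributes *k* rows with the death indicator `Y = 1`
#' on the last; a living child contributes one `Y = 0` row per bin fully
#' survived at the survey date. The bin a living child currently occupies is
#' censored at entry and contributes no row, and a child's censored later
#' bins are never included.
#'
#' Each row carries the covariates used by the hazard model: birth year, SDI
#' of the country at birth, the mother's dead-to-ever-born ratio at survey
#' (`cd_over_ceb`), the number of her children already born at this child's
#' birth (`ceb_at_birth`, counting all births with `birth_year <=` this
#' child's, so same-year siblings and the index child count), and the
#' mother's age at the birth.
#'
#' @param children CBH child table (see [read_cbh_children()]).
#' @param mothers Mother table; every `mother_id` in `children` must appear.
#' @param sdi_table Optional country-year SDI table; when `NULL` the `sdi`
#'   column is `NA` (sufficient for direct tabulation).
#' @param scheme An [age_bin_scheme()].
#' @param on_missing_sdi `"error"` or `"skip"`: what to do with children
#'   whose (country, birth year) has no SDI row. Skipped children are counted
#'   in attribute `"n_skipped_sdi"`.
#' @param quiet Suppress data-quality messages.
#' @return A `data.table`, one row per (child, bin) exposure, with columns
#'   `child_id, mother_id, bin_index, bin_label, Y, birth_year, sdi,
#'   cd_over_ceb, ceb_at_birth, mother_age_at_birth, survey_id, country,
#'   region, survey_year, survey_weight` (plus `admin1_area` when present).
#' @export
reshape_to_person_period <- function(children, mothers, sdi_table = NULL,
                                     scheme = age_bin_scheme(),
                                     on_missing_sdi = c("error", "skip"),
                                     quiet = FALSE) {
  on_missing_sdi <- match.arg(on_missing_sdi)
  ch <- data.table::as.data.table(children)
  assert_cols(ch, c("child_id", "mother_id", "birth_year", "alive"),
              "CBH child table")
  mo <- clean_mothers(mothers, quiet = quiet)

  # carry all mother attributes (arbitrary grouping keys included); child
  # columns win on a name clash
  keep_cols <- c("mother_id",
                 setdiff(names(mo), c("mother_id", names(ch))))
  ch <- merge(ch, mo[, keep_cols, with = FALSE], by = "mother_id")
  if (nrow(ch) == 0) stop("no children matched a valid mother record")
  if (any(ch$birth_year > ch$survey_year)) {
    stop("child birth_year after mother's survey_year")
  }

  A <- n_bins(scheme)
  died <- !as.logical(ch$alive)

  # Death bin (0 = died beyond the last bin, i.e. survived all of them).
  death_bin <- rep(NA_integer_, nrow(ch))
  if (any(died)) {
    assert_cols(ch, c("aod_unit", "aod_value"), "CBH child table (deaths)")
    death_bin[died] <- assign_age_bin(ch$aod_unit[died], ch$aod_value[died],
                                      scheme)
  }

  # Age in days for exposure of living children (and deaths beyond the last
  # bin, which observed every bin). Children reported with whole-year ages
  # only are handled at year resolution and counted.
  n_year_only <- 0L
  age_days <- rep(NA_real_, nrow(ch))
  alive_like <- !died | (died & death_bin == 0L)
  if (any(alive_like)) {
    am <- if ("age_months" %in% names(ch)) as.numeric(ch$age_months) else
      rep(NA_real_, nrow(ch))
    use_year <- alive_like & !died & is.na(am)
    n_year_only <- sum(use_year)
    am[use_year] <- 12 * (ch$survey_year[use_year] - ch$birth_year[use_year])
    age_days[alive_like & !died] <- round(30.44 * am[alive_like & !died])
    age_days[died & death_bin == 0L] <- scheme$end[A]
  }
  if (n_year_only > 0 && !quiet) {
    message(sprintf(
      "reshape_to_person_period: %d living child(ren) without age_months; exposure computed from whole-year ages",
      n_year_only))
  }

  n_rows <- integer(nrow(ch))
  n_rows[died & death_bin > 0L] <- death_bin[died & death_bin > 0L]
  n_rows[alive_like] <- pmin(bins_completed(age_days[alive_like], scheme), A)

  # Covariates computed before expansion.
  ch[, "cd_over_ceb" := ifelse(ceb > 0, cd / ceb, 0)]
  ch[, "ceb_at_birth" := data.table::frank(birth_year, ties.method = "max"),
     by = "mother_id"]
  ch[, "mother_age_at_birth" := age_at_survey - (survey_year - birth_year)]

  idx <- rep(seq_len(nrow(ch)), n_rows)
  pp <- ch[idx]
  pp[, "bin_index" := sequence(n_rows)]
  pp[, "Y" := as.integer(rep(died & death_bin > 0L, n_rows) &
                           pp$bin_index == rep(death_bin, n_rows))]
  pp[, "bin_label" := scheme$label[pp$bin_index]]

  # SDI at (country, birth year).
  n_skipped <- 0L
  if (!is.null(sdi_table)) {
    sdi <- data.table::as.data.table(sdi_table)
    assert_cols(sdi, c("country", "year", "sdi"), "SDI table")
    pp <- merge(pp, sdi[, list(country, birth_year = year, sdi)],
                by = c("country", "birth_year"), all.x = TRUE, sort = FALSE)
    if (anyNA(pp$sdi)) {
      if (on_missing_sdi == "error") {
        stop("missing SDI for some (country, birth_year); ",
             "use on_missing_sdi = \"skip\" to drop those children")
      }
      bad_children <- unique(pp[is.na(sdi), list(child_id, mother_id)])
      n_skipped <- nrow(bad_children)
      if (!quiet) {
        message(sprintf(
          "reshape_to_person_period: skipped %d child(ren) with missing SDI",
          n_skipped))
      }
      pp <- pp[!is.na(sdi)]
    }
  } else {
    pp[, "sdi" := NA_real_]
  }

  base_cols <- c("child_id", "mother_id", "bin_index", "bin_label", "Y",
                 "birth_year", "sdi", "cd_over_ceb", "ceb_at_birth",
                 "mother_age_at_birth", "survey_id", "country", "region",
                 "admin1_area", "survey_year", "survey_weight")
  extra_cols <- setdiff(keep_cols, c(base_cols, "mother_id", "age_at_survey",
                                     "ceb", "cd"))
  out_cols <- intersect(c(base_cols, extra_cols), names(pp))
  pp <- pp[, out_cols, with = FALSE]
  data.table::setorder(pp, mother_id, child_id, bin_index)
  data.table::setattr(pp, "n_skipped_sdi", n_skipped)
  data.table::setattr(pp, "n_year_only_ages", n_year_only)
  pp[]
}

#' Directly tabulate discrete hazards from complete birth histories
#'
#' Counts, for each group, birth period, and age bin, the children entering
#' the bin (`n`), the deaths within it (`d`), and the empirical hazard
#' `q = d / n`. This is the direct estimator used to validate indirect
#' estimates.
#'
#' @param children,mothers CBH tables as in [reshape_to_person_period()].
#' @param scheme An [age_bin_scheme()].
#' @param group_by Character vector of mother columns to group by
#'   (e.g. `"country"` or `c("country", "admin1_area")`).
#' @param period_width Width of birth-year pooling periods in years, 1
#'   (annual) or 5 (used for sparse subnational tabulations). Periods are
#'   calendar blocks `floor(year / width) * width`.
#' @return A `data.table` with columns `group_by..., year` (period start),
#'   `bin_index, bin_label, n, d, q`; cells with no entrants carry `n = 0`
#'   and `q = NA`.
#' @export
tabulate_direct_hazards <- function(children, mothers,
                                    scheme = age_bin_scheme(),
                                    group_by = "country",
                                    period_width = 1) {
  stopifnot(period_width %in% c(1, 5))
  pp <- reshape_to_person_period(children, mothers, sdi_table = NULL,
                                 scheme = scheme, quiet = TRUE)
  assert_cols(pp, group_by, "person-period table")
  pp[, "year" := as.integer(floor(birth_year / period_width) * period_width)]
  agg <- pp[, list(n = .N, d = sum(Y)),
            by = c(group_by, "year", "bin_index")]
  # Report empty cells explicitly over the observed group x period grid.
  grid <- unique(agg[, c(group_by, "year"), with = FALSE])
  grid <- grid[, data.table::CJ(bin_index = seq_len(n_bins(scheme))),
               by = c(group_by, "year")]
  out <- merge(grid, agg, by = c(group_by, "year", "bin_index"), all.x = TRUE)
  out[is.na(n), c("n", "d") := list(0L, 0L)]
  out[, "q" := ifelse(n > 0, d / n, NA_real_)]
  out[, "bin_label" := scheme$label[bin_index]]
  data.table::setorderv(out, c(group_by, "year", "bin_index"))
  out[]
}
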
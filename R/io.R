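#' Read birth-history tables from delimited text
#'
#' Thin wrappers around [data.table::fread()] that check required columns.
#' The expected layouts are:
#' \describe{
#'   \item{children (CBH)}{`child_id, mother_id, birth_year, alive (0/1),
#'     aod_unit, aod_value, age_months`. `aod_unit`/`aod_value` are populated
#'     only for dead children, `age_months` only for living children.}
#'   \item{mothers}{`mother_id, survey_id, country, region, admin1_area,
#'     survey_year, age_at_survey, ceb, cd, survey_weight` (`region` and
#'     `admin1_area` optional).}
#'   \item{SDI}{`country, year, sdi` with `sdi` on `[0, 1]`.}
#' }
#'
#' @param path File path of a delimited text table.
#' @return A `data.table`.
#' @name read_birth_histories
NULL

#' @rdname read_birth_histories
#' @export
read_cbh_children <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, c("child_id", "mother_id", "birth_year", "alive"),
              "CBH child table")
  dt
}

#' @rdname read_birth_histories
#' @export
read_mothers <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, c("mother_id", "survey_id", "country", "survey_year",
                    "age_at_survey", "ceb", "cd"), "mother table")
  dt
}

#' @rdname read_birth_histories
#' @export
read_sdi <- function(path) {
  dt <- data.table::fread(path)
  assert_cols(dt, c("country", "year", "sdi"), "SDI table")
  if (any(dt$sdi < 0 | dt$sdi > 1, na.rm = TRUE)) {
    stop("SDI values must lie in [0, 1]")
  }
  dt
}

#' Validate and clean a mother table
#'
#' Drops records violating basic integrity rules (missing CEB, `cd > ceb`,
#' negative weights, implausible ages) with a logged count rather than
#' silently; the number of dropped rows is attached as attribute
#' `"n_dropped"`.
#'
#' @param mothers Mother table (see [read_mothers()]).
#' @param quiet Suppress the message about dropped rows.
#' @return Cleaned `data.table` of mothers.
#' @export
clean_mothers <- function(mothers, quiet = FALSE) {
  mo <- data.table::as.data.table(mothers)
  assert_cols(mo, c("mother_id", "survey_id", "country", "survey_year",
                    "age_at_survey", "ceb", "cd"), "mother table")
  if (!"survey_weight" %in% names(mo)) mo[, "survey_weight" := 1]
  if (!"region" %in% names(mo)) mo[, "region" := "all"]
  ok <- !is.na(mo$ceb) & !is.na(mo$cd) & mo$cd >= 0 & mo$cd <= mo$ceb &
    mo$age_at_survey >= 10 & mo$age_at_survey <= 60 &
    !is.na(mo$survey_weight) & mo$survey_weight >= 0
  n_drop <- sum(!ok)
  if (n_drop > 0 && !quiet) {
    message(sprintf("clean_mothers: dropped %d invalid mother record(s)", n_drop))
  }
  out <- mo[ok]
  data.table::setattr(out, "n_dropped", n_drop)
  out
}
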
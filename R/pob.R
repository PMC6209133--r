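#' Tabulate empirical probability-of-birth (POB) distributions
#'
#' For each (region, mother's age at survey, CEB class) cell, tabulates the
#' distribution of the mothers' recorded births over years prior to the
#' survey `t = survey_year - birth_year`, normalised over
#' `t in [0, max_years_prior]`. These distributions give the probability
#' that a mother with given attributes had a birth `t` years before the
#' survey, and are used both to weight hypothetical children and to impute
#' CEB at birth.
#'
#' CEB classes are exact counts 0 through `ceb_cap - 1` with `ceb_cap`-plus
#' pooled (default 8+); maternal age is in single years. Cells with no
#' births are resolved at lookup time by backoff: pool CEB classes, then
#' pool ages within one year, then pool regions.
#'
#' @param children,mothers CBH tables ([read_cbh_children()],
#'   [read_mothers()]); mothers need a `region` column (or supply
#'   `region_map`).
#' @param region_map Optional named character vector mapping `country` to
#'   region; overrides any `region` column.
#' @param max_years_prior Truncation horizon for the distributions (years).
#' @param ceb_cap CEB value at and above which classes are pooled.
#' @param period_width If non-`NULL`, instead of a lookup table, return a
#'   plain tabulation additionally stratified by survey-year period
#'   (`floor(survey_year / period_width) * period_width`), for inspecting
#'   the stationarity of the distributions. Such a table cannot be used with
#'   [lookup_pob()].
#' @return An object of class `pob_table` (or a plain `data.table` when
#'   `period_width` is given).
#' @export
tabulate_pob <- function(children, mothers, region_map = NULL,
                         max_years_prior = 25, ceb_cap = 8,
                         period_width = NULL) {
  ch <- data.table::as.data.table(children)
  assert_cols(ch, c("mother_id", "birth_year"), "CBH child table")
  mo <- clean_mothers(mothers, quiet = TRUE)
  if (!is.null(region_map)) {
    mo[, "region" := unname(region_map[as.character(country)])]
    if (anyNA(mo$region)) stop("region_map does not cover all countries")
  }
  b <- merge(ch[, list(mother_id, birth_year)],
             mo[, list(mother_id, region, age = as.integer(age_at_survey),
                       ceb_class = pmin(as.integer(ceb), ceb_cap),
                       survey_year)],
             by = "mother_id")
  b[, "t" := as.integer(survey_year - birth_year)]
  b <- b[t >= 0 & t <= max_years_prior]
  if (nrow(b) == 0) stop("no births inside the POB window")

  if (!is.null(period_width)) {
    b[, "survey_period" := as.integer(floor(survey_year / period_width) *
                                        period_width)]
    out <- b[, list(births = .N),
             by = c("region", "survey_period", "age", "ceb_class", "t")]
    out[, "pob" := births / sum(births),
        by = c("region", "survey_period", "age", "ceb_class")]
    data.table::setorderv(out, c("region", "survey_period", "age",
                                 "ceb_class", "t"))
    return(out[])
  }

  l0 <- b[, list(births = .N), by = c("region", "age", "ceb_class", "t")]
  new_pob_table(l0, max_years_prior = max_years_prior, ceb_cap = ceb_cap)
}

# Construct the layered lookup object from level-0 counts. Each level keeps
# the normalised probabilities and their within-cell cumulative sums (for
# tail lookups); backoff levels are count-weighted pools of the level below.
new_pob_table <- function(l0, max_years_prior, ceb_cap) {
  finish <- function(dt, keys) {
    dt <- dt[births > 0]
    dt[, "pob" := births / sum(births), by = keys]
    data.table::setorderv(dt, c(keys, "t"))
    dt[, "F" := cumsum(pob), by = keys]
    data.table::setkeyv(dt, c(keys, "t"))
    dt[]
  }
  k0 <- c("region", "age", "ceb_class")
  l0 <- finish(data.table::as.data.table(l0), k0)
  l1 <- l0[, list(births = sum(births)), by = c("region", "age", "t")]
  l1 <- finish(l1, c("region", "age"))
  l2 <- data.table::rbindlist(lapply(-1:1, function(s) {
    l1[, list(region, age = age + s, t, births)]
  }))
  l2 <- l2[, list(births = sum(births)), by = c("region", "age", "t")]
  l2 <- finish(l2, c("region", "age"))
  l3 <- l2[, list(births = sum(births)), by = c("age", "t")]
  l3 <- finish(l3, "age")
  structure(list(l0 = l0, l1 = l1, l2 = l2, l3 = l3,
                 max_years_prior = max_years_prior, ceb_cap = ceb_cap),
            class = "pob_table")
}

#' @export
print.pob_table <- function(x, ...) {
  cat(sprintf("POB table: %d populated (region, age, CEB) cells, horizon %d years, CEB classes 0-%d+\n",
              data.table::uniqueN(x$l0[, list(region, age, ceb_class)]),
              x$max_years_prior, x$ceb_cap))
  invisible(x)
}

# Resolve which backoff level serves each query row; returns an integer
# 0..3 (or NA when even the region-pooled level has nothing).
resolve_pob_level <- function(table, q) {
  lvl <- rep(NA_integer_, nrow(q))
  has0 <- !is.na(table$l0[q, on = c("region", "age", "ceb_class"),
                          mult = "first", which = TRUE])
  lvl[has0] <- 0L
  for (k in 1:3) {
    tbl <- table[[paste0("l", k)]]
    keys <- if (k < 3) c("region", "age") else "age"
    idx <- is.na(lvl)
    if (!any(idx)) break
    hask <- !is.na(tbl[q[idx], on = keys, mult = "first", which = TRUE])
    lvl[idx][hask] <- k
  }
  lvl
}

pob_query <- function(table, region, age, ceb, t) {
  n <- max(length(region), length(age), length(ceb), length(t))
  data.table::data.table(
    region = rep_len(as.character(region), n),
    age = rep_len(as.integer(age), n),
    ceb_class = pmin(rep_len(as.integer(ceb), n), table$ceb_cap),
    t = rep_len(as.integer(t), n))
}

#' Look up probability-of-birth values
#'
#' Returns the POB for each (region, age at survey, CEB, years-prior) query,
#' using the exact cell when populated and otherwise backing off in order:
#' pool CEB classes, pool ages within one year, pool regions. Queries beyond
#' the table's horizon return 0; queries unresolved after full backoff
#' return 0 with a warning reporting how many.
#'
#' @param table A `pob_table` from [tabulate_pob()].
#' @param region,age,ceb,t Query vectors (recycled to a common length);
#'   `t >= 0` required.
#' @return Numeric vector of probabilities.
#' @export
lookup_pob <- function(table, region, age, ceb, t) {
  stopifnot(inherits(table, "pob_table"))
  if (any(t < 0)) stop("years prior to survey must be >= 0")
  q <- pob_query(table, region, age, ceb, t)
  lvl <- resolve_pob_level(table, q)
  val <- numeric(nrow(q))
  for (k in 0:3) {
    idx <- which(lvl == k)
    if (!length(idx)) next
    tbl <- table[[paste0("l", k)]]
    keys <- switch(as.character(k),
                   "0" = c("region", "age", "ceb_class", "t"),
                   "1" = c("region", "age", "t"),
                   "2" = c("region", "age", "t"),
                   "3" = c("age", "t"))
    v <- tbl[q[idx], on = keys, x.pob]
    val[idx] <- data.table::fifelse(is.na(v), 0, v)
  }
  val[q$t > table$max_years_prior] <- 0
  n_unres <- sum(is.na(lvl))
  if (n_unres > 0) {
    warning(sprintf("lookup_pob: %d query row(s) unresolved after backoff; returning 0",
                    n_unres))
    val[is.na(lvl)] <- 0
  }
  val
}

# Tail probability sum_{t' > t} POB(t') for each query, resolved with the
# same backoff as lookup_pob. Uses a rolling join on the within-cell
# cumulative distribution.
pob_tail <- function(table, region, age, ceb, t) {
  q <- pob_query(table, region, age, ceb, t)
  lvl <- resolve_pob_level(table, q)
  F <- numeric(nrow(q))
  for (k in 0:3) {
    idx <- which(lvl == k)
    if (!length(idx)) next
    tbl <- table[[paste0("l", k)]]
    keys <- switch(as.character(k),
                   "0" = c("region", "age", "ceb_class", "t"),
                   "1" = c("region", "age", "t"),
                   "2" = c("region", "age", "t"),
                   "3" = c("age", "t"))
    v <- tbl[q[idx], on = keys, roll = TRUE, x.F]
    F[idx] <- data.table::fifelse(is.na(v), 0, v)
  }
  F[is.na(lvl)] <- 1  # nothing known: no expected earlier births
  pmax(0, pmin(1, 1 - F))
}

#' Impute expected CEB at the time of a (hypothetical) birth
#'
#' For a mother observed with `ceb` children at the survey, the expected
#' number of her children already born at a birth `t = survey_year -
#' birth_year` years before the survey is taken as one (the index child)
#' plus `ceb` times the POB mass at years prior greater than `t`, capped at
#' her reported CEB. A mother with `ceb = 0` yields 1 (the hypothetical
#' child itself).
#'
#' @param table A `pob_table`.
#' @param mothers Mother table (needs `region`, `age_at_survey`, `ceb`,
#'   `survey_year`).
#' @param birth_year Hypothetical birth year(s), recycled against mothers;
#'   must not exceed `survey_year`.
#' @return Numeric vector of expected CEB-at-birth values (>= 1).
#' @export
impute_ceb_at_birth <- function(table, mothers, birth_year) {
  mo <- data.table::as.data.table(mothers)
  assert_cols(mo, c("age_at_survey", "ceb", "survey_year"), "mother table")
  if (!"region" %in% names(mo)) mo[, "region" := "all"]
  n <- max(nrow(mo), length(birth_year))
  by <- rep_len(birth_year, n)
  sy <- rep_len(mo$survey_year, n)
  if (any(by > sy)) stop("birth_year after survey_year")
  t <- as.integer(sy - by)
  tail <- pob_tail(table, rep_len(mo$region, n),
                   rep_len(mo$age_at_survey, n), rep_len(mo$ceb, n), t)
  ceb <- rep_len(as.numeric(mo$ceb), n)
  data.table::fifelse(ceb == 0, 1, pmin(1 + ceb * tail, pmax(ceb, 1)))
}

#' Read and write POB tables as delimited text
#'
#' The on-disk format is one row per populated level-0 cell-year:
#' `region, age, ceb_class, t, births, pob`. Externally produced tables can
#' be dropped in provided they use this layout (`births` may be a
#' pseudo-count; backoff pooling weights cells by it).
#'
#' @param table A `pob_table`.
#' @param path File path.
#' @param max_years_prior,ceb_cap Metadata needed to rebuild the lookup
#'   object when reading.
#' @name pob_io
#' @export
write_pob_table <- function(table, path) {
  stopifnot(inherits(table, "pob_table"))
  data.table::fwrite(table$l0[, list(region, age, ceb_class, t, births, pob)],
                     path)
  invisible(path)
}

#' @rdname pob_io
#' @export
read_pob_table <- function(path, max_years_prior = 25, ceb_cap = 8) {
  l0 <- data.table::fread(path)
  assert_cols(l0, c("region", "age", "ceb_class", "t", "births"), "POB table")
  new_pob_table(l0[, list(region, age, ceb_class, t, births)],
                max_years_prior = max_years_prior, ceb_cap = ceb_cap)
}
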
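#' Age-bin scheme for discrete-time survival analysis
#'
#' Defines the discrete age bins over which child mortality hazards are
#' modelled. The default scheme uses seven bins chosen to align with how ages
#' at death are reported in birth-history surveys (days under one month,
#' months under two years, whole years thereafter): neonatal (NN, birth to 28
#' days), two post-neonatal bins (PNN1, 29 days to 5 months; PNN2, 6 to 11
#' months), and single-year bins for ages 1 through 4. Intervals are
#' half-open `[start, end)` in days; a death at an exact boundary belongs to
#' the later bin.
#'
#' @param bins A `data.frame` with columns `label`, `start`, `end` (ages in
#'   days), or `NULL` for the default under-five scheme.
#' @return An object of class `age_bin_scheme`: a `data.table` with columns
#'   `bin_index`, `label`, `start`, `end`.
#' @examples
#' sc <- age_bin_scheme()
#' sc$label
#' @export
age_bin_scheme <- function(bins = NULL) {
  if (is.null(bins)) {
    bins <- data.frame(
      label = c("NN", "PNN1", "PNN2", "1yr", "2yr", "3yr", "4yr"),
      start = c(0L, 29L, 183L, 365L, 730L, 1095L, 1460L),
      end   = c(29L, 183L, 365L, 730L, 1095L, 1460L, 1825L)
    )
  }
  assert_cols(bins, c("label", "start", "end"), "age bin table")
  dt <- data.table::as.data.table(bins)[, c("label", "start", "end"), with = FALSE]
  data.table::setorder(dt, start)
  if (dt$start[1] != 0) stop("first age bin must start at age 0 days")
  if (anyDuplicated(dt$label)) stop("age bin labels must be unique")
  if (any(dt$end <= dt$start)) stop("age bins must have end > start")
  if (nrow(dt) > 1 && any(dt$start[-1] != dt$end[-nrow(dt)])) {
    stop("age bins must be contiguous and non-overlapping")
  }
  dt[, "bin_index" := seq_len(.N)]
  data.table::setcolorder(dt, c("bin_index", "label", "start", "end"))
  class(dt) <- c("age_bin_scheme", class(dt))
  dt[]
}

n_bins <- function(scheme) nrow(scheme)

#' Convert a coded age at death to days
#'
#' Survey age-at-death codes use days for deaths under one month, months
#' under two years, and whole years beyond. Conversion to days is
#' centralised here: months are converted as `round(30.44 * m)` and years as
#' `round(365.25 * y)`. Swapping the convention only requires changing this
#' function.
#'
#' @param unit Character vector in `c("days", "months", "years")`.
#' @param value Numeric vector of coded ages (same length as `unit`).
#' @return Integer vector of ages in days.
#' @export
aod_to_days <- function(unit, value) {
  unit <- as.character(unit)
  bad <- !unit %in% c("days", "months", "years")
  if (any(bad)) stop("unknown age-at-death unit(s): ",
                     paste(unique(unit[bad]), collapse = ", "))
  if (any(value < 0, na.rm = TRUE)) stop("negative age at death")
  days <- ifelse(unit == "days", value,
          ifelse(unit == "months", round(30.44 * value), round(365.25 * value)))
  as.integer(days)
}

#' Assign a coded age at death to an age bin
#'
#' @param unit,value Coded age at death (see [aod_to_days()]); vectorised.
#' @param scheme An [age_bin_scheme()].
#' @return Integer vector of bin indices (1-based). Ages at or beyond the end
#'   of the last bin return the sentinel `0L`, meaning "survived all
#'   under-five bins".
#' @examples
#' assign_age_bin("days", 15)   # 1 (NN)
#' assign_age_bin("months", 14) # 4 (1yr)
#' assign_age_bin("years", 6)   # 0 (beyond under-5)
#' @export
assign_age_bin <- function(unit, value, scheme = age_bin_scheme()) {
  days <- aod_to_days(unit, value)
  idx <- findInterval(days, scheme$start)
  idx[days >= scheme$end[nrow(scheme)]] <- 0L
  as.integer(idx)
}

# Number of bins fully completed by a child of age `days` (end <= days).
bins_completed <- function(days, scheme) {
  findInterval(days, scheme$end)
}
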
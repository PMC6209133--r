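# Independent brute-force oracles used to check the vectorized
# implementations. These deliberately share no code with the package
# internals: plain loops and direct interval arithmetic only.

# Bin index containing an age in days, by explicit interval walk.
oracle_bin_of_days <- function(days, scheme) {
  for (i in seq_len(nrow(scheme))) {
    if (days >= scheme$start[i] && days < scheme$end[i]) return(i)
  }
  0L
}

# Person-period rows for one child by walking bins one at a time.
# Returns a data.frame of (bin_index, Y).
oracle_bin_walk <- function(alive, aod_unit = NA, aod_value = NA,
                            age_months = NA, scheme = age_bin_scheme()) {
  rows <- data.frame(bin_index = integer(), Y = integer())
  if (!alive) {
    d <- switch(aod_unit, days = aod_value,
                months = round(30.44 * aod_value),
                years = round(365.25 * aod_value))
    db <- oracle_bin_of_days(d, scheme)
    if (db == 0L) {                      # died beyond under-5: all bins survived
      for (i in seq_len(nrow(scheme))) {
        rows <- rbind(rows, data.frame(bin_index = i, Y = 0L))
      }
    } else {
      for (i in seq_len(db)) {
        rows <- rbind(rows,
                      data.frame(bin_index = i, Y = as.integer(i == db)))
      }
    }
  } else {
    aged <- round(30.44 * age_months)
    for (i in seq_len(nrow(scheme))) {
      if (scheme$end[i] <= aged) {
        rows <- rbind(rows, data.frame(bin_index = i, Y = 0L))
      }
    }
  }
  rows
}

# Survival to bin entry by explicit loop.
oracle_survival <- function(q) {
  s <- numeric(length(q))
  for (a in seq_along(q)) {
    s[a] <- 1
    if (a > 1) for (b in seq_len(a - 1)) s[a] <- s[a] * (1 - q[b])
  }
  s
}

# Cumulative mortality over bins by explicit loop.
oracle_combine <- function(q) {
  surv <- 1
  for (qa in q) surv <- surv * (1 - qa)
  1 - surv
}

# Metric suite computed by direct formula evaluation with loops/sorting.
oracle_metrics <- function(est, val, w) {
  e <- est - val
  me <- sum(w * e) / sum(w)
  sde <- sqrt(sum(w * (e - me)^2) / sum(w))
  wmed <- function(x, wt) {
    o <- order(x); x <- x[o]; wt <- wt[o]
    cw <- cumsum(wt)
    x[min(which(cw >= 0.5 * sum(wt)))]
  }
  pos <- val > 0
  mre <- wmed((est / val)[pos], w[pos])
  mape <- wmed((100 * abs(e) / val)[pos], w[pos])
  qbar <- sum(w * val) / sum(w)
  r2 <- 1 - sum(w * e^2) / sum(w * (val - qbar)^2)
  list(me = me, sde = sde, mre = mre, mape = mape, r2 = r2)
}

# Random CBH fixture: n children with random fates, one mother each by
# default (mothers_per_child > 1 groups children under shared mothers).
random_cbh <- function(n, seed, survey_year = 2010, n_mothers = n) {
  set.seed(seed)
  mother_id <- sprintf("m%05d", sample.int(n_mothers, n, replace = TRUE))
  birth_year <- sample((survey_year - 20):survey_year, n, replace = TRUE)
  alive <- stats::runif(n) < 0.8
  aod_unit <- rep(NA_character_, n)
  aod_value <- rep(NA_real_, n)
  dead <- which(!alive)
  unit_pick <- sample(c("days", "months", "years"), length(dead),
                      replace = TRUE)
  aod_unit[dead] <- unit_pick
  aod_value[dead] <- ifelse(unit_pick == "days", sample(0:40, length(dead), TRUE),
                     ifelse(unit_pick == "months", sample(0:30, length(dead), TRUE),
                            sample(0:7, length(dead), TRUE)))
  age_months <- ifelse(alive, 12 * (survey_year - birth_year), NA_real_)
  children <- data.frame(
    child_id = sprintf("c%05d", seq_len(n)), mother_id, birth_year,
    alive = as.integer(alive), aod_unit, aod_value, age_months)
  mo_ids <- unique(mother_id)
  tots <- tapply(!alive, mother_id, sum)[mo_ids]
  cebs <- tapply(alive, mother_id, length)[mo_ids]
  mothers <- data.frame(
    mother_id = mo_ids, survey_id = "S1", country = "X", region = "all",
    survey_year = survey_year,
    age_at_survey = pmin(25 + (survey_year - tapply(birth_year, mother_id, min)[mo_ids]), 49),
    ceb = as.integer(cebs), cd = as.integer(tots), survey_weight = 1)
  list(children = children, mothers = mothers)
}
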
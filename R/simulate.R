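#' Configuration for the synthetic birth-history generator
#'
#' Defines a complete generative model for paired CBH/SBH survey data with
#' known ground-truth hazards. The hazard model is logit-additive, matching
#' the structure of the fitted discrete-time survival model so that
#' recovery tests are well posed: for a child born in year `yr` in country
#' `c` to mother `m`,
#' `logit(q_a) = logit(baseline_q[a]) + trend_logit * (yr - ref_year) +
#'  sdi_effect * (SDI_{c,yr} - sdi_ref) + country_effect + survey_effect +
#'  frailty_m`,
#' with country, survey, and mother frailty effects drawn as independent
#' normals. A `misspecified` mode adds an age-varying frailty loading
#' (`misspec_amp * frailty_m * (a - 4) / 3`), a non-additive interaction
#' the fitted model cannot represent, for robustness exercises.
#'
#' Fertility is an age-specific annual birth probability with a hump shape
#' peaking in the mothers' twenties; defaults give a completed family size
#' of about four children, typical of the high-mortality settings the
#' method targets. SDI follows monotone country trajectories on `[0, 1]`.
#'
#' @param n_countries Number of countries.
#' @param surveys_per_country Surveys per country.
#' @param mothers_per_survey Mothers sampled per survey.
#' @param survey_years Calendar years of the surveys within each country
#'   (length `surveys_per_country`).
#' @param baseline_q Per-bin hazards at the reference year and SDI; the
#'   defaults are typical survey-era age-specific under-five hazards
#'   (about 0.031 neonatal declining to 0.003 at age four).
#' @param trend_logit Secular trend in logit hazard per calendar year.
#' @param sdi_effect Effect of SDI (per unit) on the logit hazard.
#' @param ref_year,sdi_ref Centring constants of the hazard model.
#' @param frailty_sd,survey_sd,country_sd Standard deviations of the mother
#'   frailty and survey / country intercepts (logit scale).
#' @param fertility_peak,fertility_width,fertility_level Age-specific annual
#'   birth probability `level * exp(-((age - peak) / width)^2)`.
#' @param max_ceb Maximum children per mother.
#' @param mother_age_range Ages at survey sampled uniformly from this range.
#' @param sdi_start_range,sdi_slope_range Country SDI trajectories: level at
#'   1960 drawn uniformly from `sdi_start_range`, linear annual increase
#'   drawn from `sdi_slope_range`, clamped to `[0.05, 0.95]`.
#' @param misspecified Enable the non-additive age-varying frailty loading.
#' @param misspec_amp Amplitude of that loading.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_countries = 4, surveys_per_country = 2,
                              mothers_per_survey = 5000,
                              survey_years = c(2005, 2012),
                              baseline_q = c(NN = 0.031, PNN1 = 0.015,
                                             PNN2 = 0.013, `1yr` = 0.013,
                                             `2yr` = 0.009, `3yr` = 0.006,
                                             `4yr` = 0.003),
                              trend_logit = -0.03, sdi_effect = -2.5,
                              ref_year = 2000, sdi_ref = 0.5,
                              frailty_sd = 0.25, survey_sd = 0.05,
                              country_sd = 0.10,
                              fertility_peak = 23, fertility_width = 8,
                              fertility_level = 0.28, max_ceb = 12,
                              mother_age_range = c(15, 49),
                              sdi_start_range = c(0.15, 0.45),
                              sdi_slope_range = c(0.003, 0.008),
                              misspecified = FALSE, misspec_amp = 0.5,
                              seed = 1) {
  stopifnot(length(survey_years) == surveys_per_country,
            all(baseline_q > 0 & baseline_q < 1),
            fertility_level >= 0, max_ceb >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

fertility_rate <- function(age, cfg) {
  cfg$fertility_level * exp(-((age - cfg$fertility_peak) /
                                cfg$fertility_width)^2)
}

# Number of default-scheme bins fully completed by a child whose age at
# survey is a whole number of years.
bins_completed_years <- function(T) {
  lut <- c(0L, 3L, 4L, 5L, 6L, 7L)
  lut[pmin(T, 5L) + 1L]
}

# True marginal hazard per (country, year, bin): the entrant-weighted
# population hazard, integrating the mother frailty out numerically
# (fine z grid), with survey effects at their mean of zero and the
# realized country effect included.
marginal_truth <- function(cfg, sdi, country_effects, years) {
  z <- seq(-6, 6, length.out = 241)
  wz <- stats::dnorm(z); wz <- wz / sum(wz)
  A <- length(cfg$baseline_q)
  grid <- data.table::CJ(country = names(country_effects), year = years)
  grid <- merge(grid, sdi, by.x = c("country", "year"),
                by.y = c("country", "year"))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    eta0 <- logit(cfg$baseline_q) +
      cfg$trend_logit * (grid$year[i] - cfg$ref_year) +
      cfg$sdi_effect * (grid$sdi[i] - cfg$sdi_ref) +
      country_effects[[grid$country[i]]]
    load <- if (cfg$misspecified) {
      cfg$misspec_amp * (seq_len(A) - 4) / 3
    } else rep(0, A)
    qz <- invlogit(outer(eta0, cfg$frailty_sd * z, "+") +
                     outer(load * cfg$frailty_sd, z))
    Sz <- rbind(1, apply(1 - qz, 2, cumprod))[seq_len(A), , drop = FALSE]
    qbar <- as.vector((qz * Sz) %*% wz) / as.vector(Sz %*% wz)
    out[[i]] <- data.table::data.table(
      country = grid$country[i], year = grid$year[i],
      bin_index = seq_len(A), true_q = qbar)
  }
  data.table::rbindlist(out)
}

#' Simulate a paired CBH/SBH population with known ground truth
#'
#' Draws countries, SDI trajectories, surveys, mothers, their birth
#' histories, and each child's death bin sequentially from the true
#' discrete hazards of the configuration, coding ages at death in the
#' survey convention (days under one month, months under two years, years
#' beyond). Children's ages are resolved at whole calendar years, and a
#' death can only be observed in an age bin fully completed before the
#' survey; the partially entered bin is censored, consistently with the
#' person-period reshape. Fully deterministic given the configuration seed.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list of class `sbh_simulation` with elements `mothers`,
#'   `children` (CBH tables in the package's input layout), `sdi`,
#'   `surveys`, `ground_truth` (per country-year-bin true marginal hazard),
#'   and `config`.
#' @export
simulate_population <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(seed %||% cfg$seed, {
    countries <- sprintf("C%02d", seq_len(cfg$n_countries))
    c_eff <- stats::setNames(stats::rnorm(cfg$n_countries, 0, cfg$country_sd),
                             countries)
    sdi_start <- stats::runif(cfg$n_countries, cfg$sdi_start_range[1],
                              cfg$sdi_start_range[2])
    sdi_slope <- stats::runif(cfg$n_countries, cfg$sdi_slope_range[1],
                              cfg$sdi_slope_range[2])
    yr_min <- min(cfg$survey_years) - (cfg$mother_age_range[2] - 12) - 1
    yr_max <- max(cfg$survey_years)
    sdi <- data.table::CJ(country = countries, year = yr_min:yr_max)
    ci <- match(sdi$country, countries)
    sdi[, "sdi" := pmin(pmax(sdi_start[ci] + sdi_slope[ci] * (year - 1960),
                             0.05), 0.95)]

    surveys <- data.table::CJ(country = countries,
                              survey_year = cfg$survey_years)
    surveys[, "survey_id" := paste0(country, "_", survey_year)]
    surveys[, "survey_effect" := stats::rnorm(.N, 0, cfg$survey_sd)]

    # Mothers.
    n_m <- nrow(surveys) * cfg$mothers_per_survey
    mothers <- surveys[rep(seq_len(nrow(surveys)), each = cfg$mothers_per_survey)]
    mothers[, "mother_id" := sprintf("M%07d", seq_len(n_m))]
    mothers[, "age_at_survey" := sample(cfg$mother_age_range[1]:cfg$mother_age_range[2],
                                        n_m, replace = TRUE)]
    mothers[, "frailty" := stats::rnorm(n_m, 0, cfg$frailty_sd)]
    mothers[, "survey_weight" := 1]
    mothers[, "region" := "all"]

    # Births: one Bernoulli trial per (mother, age 12..age_at_survey),
    # capped at max_ceb in age order.
    n_ages <- mothers$age_at_survey - 12L + 1L
    grid <- mothers[rep(seq_len(n_m), n_ages),
                    list(mother_id, survey_id, country, survey_year,
                         age_at_survey, frailty, survey_effect)]
    grid[, "age_at_birth" := sequence(n_ages) + 11L]
    grid[, "birth_year" := survey_year - (age_at_survey - age_at_birth)]
    grid[, "born" := stats::rbinom(.N, 1, fertility_rate(age_at_birth, cfg))]
    grid[, "parity" := cumsum(born), by = "mother_id"]
    births <- grid[born == 1L & parity <= cfg$max_ceb]

    # Child hazards and sequential death sampling over completed bins.
    A <- length(cfg$baseline_q)
    births <- merge(births, sdi, by.x = c("country", "birth_year"),
                    by.y = c("country", "year"), sort = FALSE)
    data.table::setorder(births, mother_id, birth_year)
    n_c <- nrow(births)
    births[, "child_id" := sprintf("K%08d", seq_len(n_c))]
    eta_base <- cfg$trend_logit * (births$birth_year - cfg$ref_year) +
      cfg$sdi_effect * (births$sdi - cfg$sdi_ref) +
      c_eff[births$country] + births$survey_effect + births$frailty
    load <- if (cfg$misspecified) cfg$misspec_amp * (seq_len(A) - 4) / 3 else
      rep(0, A)
    qm <- invlogit(outer(eta_base, logit(cfg$baseline_q), "+") +
                     outer(births$frailty, load))
    n_full <- bins_completed_years(births$survey_year - births$birth_year)
    died_mat <- matrix(stats::runif(n_c * A), n_c, A) < qm
    died_mat[col(died_mat) > n_full] <- FALSE
    death_bin <- integer(n_c)
    for (a in rev(seq_len(A))) death_bin[died_mat[, a]] <- a

    children <- births[, list(child_id, mother_id, birth_year)]
    children[, "alive" := as.integer(death_bin == 0L)]
    children[, "age_months" := data.table::fifelse(
      death_bin == 0L, 12 * (births$survey_year - birth_year), NA_real_)]
    # Code ages at death in the survey convention; sampling the coded value
    # uniformly within the death bin's reporting range.
    children[, c("aod_unit", "aod_value") := list(NA_character_, NA_real_)]
    dd <- which(death_bin > 0L)
    if (length(dd)) {
      db <- death_bin[dd]
      unit <- c("days", "months", "months", "months", "years", "years",
                "years")[db]
      lo <- c(0, 1, 6, 12, 2, 3, 4)[db]
      hi <- c(28, 5, 11, 23, 2, 3, 4)[db]
      val <- lo + floor(stats::runif(length(dd)) * (hi - lo + 1))
      children[dd, c("aod_unit", "aod_value") := list(unit, as.numeric(val))]
    }

    # Mother SBH totals.
    tot <- children[, list(ceb = .N, cd = sum(alive == 0L)),
                    by = "mother_id"]
    mothers <- merge(mothers[, list(mother_id, survey_id, country, region,
                                    survey_year, age_at_survey,
                                    survey_weight, frailty)],
                     tot, by = "mother_id", all.x = TRUE)
    mothers[is.na(ceb), c("ceb", "cd") := 0L]
    data.table::setorder(mothers, mother_id)

    truth <- marginal_truth(cfg, sdi, as.list(c_eff), yr_min:yr_max)
    truth[, "bin_label" := names(cfg$baseline_q)[bin_index]]

    structure(list(mothers = mothers[], children = children[], sdi = sdi[],
                   surveys = surveys[], ground_truth = truth[],
                   country_effects = c_eff, config = cfg),
              class = "sbh_simulation")
  })
}

#' @export
print.sbh_simulation <- function(x, ...) {
  cat(sprintf("Synthetic birth-history population: %d mothers, %d children, %d countries, %d surveys\n",
              nrow(x$mothers), nrow(x$children),
              x$config$n_countries, nrow(x$surveys)))
  invisible(x)
}

#' Derive the summary-birth-history view of a CBH population
#'
#' Collapses child-level detail to per-mother totals: children ever born
#' and children died by the survey date. Deterministic and idempotent.
#'
#' @param mothers Mother table (attributes are carried through).
#' @param children CBH child table.
#' @param include_childless Keep mothers with no recorded children as
#'   `ceb = 0` rows.
#' @return A `data.table` in the SBH mother layout.
#' @export
derive_sbh_view <- function(mothers, children, include_childless = FALSE) {
  mo <- data.table::as.data.table(mothers)
  ch <- data.table::as.data.table(children)
  assert_cols(ch, c("mother_id", "alive"), "CBH child table")
  tot <- ch[, list(ceb = .N, cd = sum(!as.logical(alive))),
            by = "mother_id"]
  keep <- setdiff(names(mo), c("ceb", "cd", "frailty"))
  out <- merge(mo[, keep, with = FALSE], tot, by = "mother_id", all.x = TRUE)
  out[is.na(ceb), c("ceb", "cd") := 0L]
  if (!include_childless) out <- out[ceb > 0]
  data.table::setorder(out, mother_id)
  out[]
}

#' Split surveys into training and holdout sets
#'
#' The `"most-recent-per-country"` rule keeps the latest survey of each
#' country for testing and trains on the rest, the standard design for
#' out-of-sample validation of indirect estimates. Countries with a single
#' survey contribute no test survey (logged).
#'
#' @param surveys `data.table` with `survey_id`, `country`, `survey_year`.
#' @param rule Split rule; only `"most-recent-per-country"` is defined.
#' @return A list with character vectors `train` and `test` of survey ids.
#' @export
make_holdout_split <- function(surveys, rule = "most-recent-per-country") {
  rule <- match.arg(rule)
  sv <- data.table::as.data.table(surveys)
  assert_cols(sv, c("survey_id", "country", "survey_year"), "survey table")
  sv[, "n_svy" := .N, by = "country"]
  single <- unique(sv[n_svy < 2, country])
  if (length(single)) {
    message("make_holdout_split: no test survey for single-survey country(ies): ",
            paste(single, collapse = ", "))
  }
  test <- sv[n_svy >= 2, list(survey_id = survey_id[which.max(survey_year)]),
             by = "country"]$survey_id
  list(train = setdiff(sv$survey_id, test), test = test)
}
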
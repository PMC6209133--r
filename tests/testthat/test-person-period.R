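one_mother <- function(survey_year = 2010, age = 30, ceb = 1, cd = 0) {
  data.frame(mother_id = "m1", survey_id = "S1", country = "X",
             region = "all", survey_year = survey_year,
             age_at_survey = age, ceb = ceb, cd = cd, survey_weight = 1)
}
one_child <- function(alive, aod_unit = NA, aod_value = NA, age_months = NA,
                      birth_year = 2005) {
  data.frame(child_id = "c1", mother_id = "m1", birth_year = birth_year,
             alive = as.integer(alive), aod_unit = aod_unit,
             aod_value = aod_value, age_months = age_months)
}

test_that("a neonatal death yields exactly one row with Y = 1", {
  pp <- reshape_to_person_period(one_child(FALSE, "days", 15),
                                 one_mother(ceb = 1, cd = 1), quiet = TRUE)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$bin_index, 1L)
  expect_equal(pp$Y, 1L)
  expect_equal(pp$bin_label, "NN")
})

test_that("a living 36-month-old contributes the five completed bins only", {
  pp <- reshape_to_person_period(one_child(TRUE, age_months = 36),
                                 one_mother(), quiet = TRUE)
  # 36 months = 1096 days; 2yr bin ends at 1095 so five bins are complete
  expect_equal(pp$bin_index, 1:5)
  expect_equal(pp$Y, rep(0L, 5))
})

test_that("a death at 14 months yields NN..PNN2 survived and 1yr death", {
  pp <- reshape_to_person_period(one_child(FALSE, "months", 14),
                                 one_mother(ceb = 1, cd = 1), quiet = TRUE)
  expect_equal(pp$bin_index, 1:4)
  expect_equal(pp$Y, c(0L, 0L, 0L, 1L))
})

test_that("reshape matches the brute-force bin walk on random children", {
  fx <- random_cbh(400, seed = 99)
  pp <- reshape_to_person_period(fx$children, fx$mothers, quiet = TRUE)
  got <- as.data.frame(pp[, c("child_id", "bin_index", "Y")])
  want <- do.call(rbind, lapply(seq_len(nrow(fx$children)), function(i) {
    ci <- fx$children[i, ]
    rows <- oracle_bin_walk(as.logical(ci$alive), ci$aod_unit, ci$aod_value,
                            ci$age_months)
    if (nrow(rows)) cbind(child_id = ci$child_id, rows) else NULL
  }))
  want <- want[order(want$child_id, want$bin_index), ]
  got <- got[order(got$child_id, got$bin_index), ]
  rownames(want) <- rownames(got) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("per-child death indicators sum to died-under-5 status", {
  fx <- random_cbh(300, seed = 7)
  pp <- reshape_to_person_period(fx$children, fx$mothers, quiet = TRUE)
  ysum <- pp[, list(y = sum(Y)), by = "child_id"]
  merged <- merge(data.table::as.data.table(fx$children), ysum,
                  by = "child_id", all.x = TRUE)
  merged[is.na(y), y := 0L]
  died_u5 <- !as.logical(merged$alive) &
    assign_age_bin(ifelse(is.na(merged$aod_unit), "days", merged$aod_unit),
                   ifelse(is.na(merged$aod_value), 0, merged$aod_value)) > 0 &
    !as.logical(merged$alive)
  expect_equal(merged$y, as.integer(died_u5))
})

test_that("reshape is order-independent", {
  fx <- random_cbh(150, seed = 3)
  pp1 <- reshape_to_person_period(fx$children, fx$mothers, quiet = TRUE)
  perm <- sample(nrow(fx$children))
  pp2 <- reshape_to_person_period(fx$children[perm, ], fx$mothers,
                                  quiet = TRUE)
  expect_equal(pp1, pp2, ignore_attr = TRUE)
})

test_that("covariates attach per row as defined", {
  children <- data.frame(
    child_id = c("c1", "c2", "c3"), mother_id = "m1",
    birth_year = c(2000, 2000, 2004),
    alive = c(1L, 1L, 1L),
    aod_unit = NA, aod_value = NA, age_months = c(120, 120, 72))
  mothers <- one_mother(survey_year = 2010, age = 30, ceb = 3, cd = 1)
  sdi <- data.frame(country = "X", year = c(2000, 2004),
                    sdi = c(0.4, 0.48))
  pp <- reshape_to_person_period(children, mothers, sdi, quiet = TRUE)
  # same-year twins both count in ceb_at_birth
  expect_equal(unique(pp[child_id == "c1", ceb_at_birth]), 2L)
  expect_equal(unique(pp[child_id == "c2", ceb_at_birth]), 2L)
  expect_equal(unique(pp[child_id == "c3", ceb_at_birth]), 3L)
  expect_equal(unique(pp[child_id == "c3", mother_age_at_birth]), 24)
  expect_true(all(abs(pp$cd_over_ceb - 1 / 3) < 1e-12))
  expect_equal(unique(pp[child_id == "c1", sdi]), 0.4)
})

test_that("missing SDI errors by default and skips when asked", {
  children <- one_child(TRUE, age_months = 60, birth_year = 2005)
  sdi <- data.frame(country = "X", year = 1999, sdi = 0.3)
  expect_error(reshape_to_person_period(children, one_mother(), sdi,
                                        quiet = TRUE), "missing SDI")
  pp <- reshape_to_person_period(children, one_mother(), sdi,
                                 on_missing_sdi = "skip", quiet = TRUE)
  expect_equal(nrow(pp), 0L)
  expect_equal(attr(pp, "n_skipped_sdi"), 1L)
})

test_that("direct tabulation counts entrants and deaths", {
  # 10 children born the same year, 1 NN death, others survive everything
  children <- data.frame(
    child_id = sprintf("c%d", 1:10), mother_id = sprintf("m%d", 1:10),
    birth_year = 2000, alive = c(0L, rep(1L, 9)),
    aod_unit = c("days", rep(NA, 9)), aod_value = c(10, rep(NA, 9)),
    age_months = c(NA, rep(120, 9)))
  mothers <- data.frame(
    mother_id = sprintf("m%d", 1:10), survey_id = "S1", country = "X",
    region = "all", survey_year = 2010, age_at_survey = 30,
    ceb = 1, cd = c(1, rep(0, 9)), survey_weight = 1)
  dh <- tabulate_direct_hazards(children, mothers)
  expect_equal(dh[bin_index == 1, q], 0.1)
  expect_equal(dh[bin_index == 1, n], 10L)
  expect_true(all(dh[bin_index > 1, q] == 0))
  expect_equal(dh[bin_index == 2, n], 9L)
  # pooling single-year data into a 5-year period changes nothing
  dh5 <- tabulate_direct_hazards(children, mothers, period_width = 5)
  expect_equal(dh5$q, dh$q)
  expect_equal(dh5$n, dh$n)
  expect_equal(unique(dh5$year), 2000L)
})

test_that("direct tabulation recovers constant hazards from simulation", {
  cfg <- simulation_config(n_countries = 1, surveys_per_country = 1,
                           mothers_per_survey = 4000, survey_years = 2010,
                           trend_logit = 0, sdi_effect = 0, frailty_sd = 0,
                           survey_sd = 0, country_sd = 0, seed = 5)
  sim <- simulate_population(cfg)
  dh <- tabulate_direct_hazards(sim$children, sim$mothers)
  pooled <- dh[, list(n = sum(n), d = sum(d)), by = "bin_index"]
  pooled[, q := d / n]
  for (a in seq_len(7)) {
    q0 <- cfg$baseline_q[a]
    se <- sqrt(q0 * (1 - q0) / pooled$n[a])
    expect_lt(abs(pooled$q[a] - q0), 3 * se + 1e-12)
  }
  # deaths in the tabulation match CD totals (all deaths are under 5 here)
  expect_equal(sum(dh$d), sum(sim$mothers$cd))
})
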
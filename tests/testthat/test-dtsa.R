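# A compact, deterministic simulated population shared by the model tests.
small_sim <- function(seed = 2, mothers = 600, countries = 2,
                      surveys = 2, ...) {
  cfg <- simulation_config(n_countries = countries,
                           surveys_per_country = surveys,
                           mothers_per_survey = mothers,
                           survey_years = if (surveys == 2) c(2004, 2010) else 2010,
                           seed = seed, ...)
  simulate_population(cfg)
}

test_that("the saturated baseline equals per-bin death fractions", {
  sim <- small_sim()
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  bl <- suppressWarnings(fit_baseline(pp))
  cnt <- pp[, list(d = sum(Y), n = .N), by = "bin_index"]
  data.table::setorder(cnt, bin_index)
  expect_equal(bl$q, cnt$d / cnt$n, tolerance = 1e-9)
  expect_equal(bl$counts$d, cnt$d)
})

test_that("bins with no deaths are flagged divergent and reported as 0", {
  pp <- data.table::data.table(bin_index = rep(1:2, c(50, 40)),
                               Y = c(rep(0:1, c(45, 5)), rep(0L, 40)))
  bl <- suppressWarnings(fit_baseline(pp, age_bin_scheme(
    data.frame(label = c("a", "b"), start = c(0, 29), end = c(29, 365)))))
  expect_equal(bl$q, c(0.1, 0))
  expect_equal(bl$divergent, c(FALSE, TRUE))
})

test_that("bins with no entrants are reported missing", {
  pp <- data.table::data.table(bin_index = rep(1L, 30),
                               Y = rep(0:1, c(27, 3)))
  bl <- suppressWarnings(fit_baseline(pp))
  expect_equal(bl$q[1], 0.1, tolerance = 1e-9)
  expect_true(all(is.na(bl$q[2:7])))
})

test_that("baseline predictions pass hazards through by bin", {
  pp <- data.table::data.table(bin_index = rep(1:7, each = 100),
                               Y = as.integer(rep(seq(0.5, 0.02, length.out = 7),
                                                  each = 100) >
                                                stats::runif(700)))
  set.seed(1)
  bl <- suppressWarnings(fit_baseline(pp))
  pr <- predict_hazard(bl, data.frame(bin_index = c(3, 1, 7)))
  expect_equal(pr$point, bl$q[c(3, 1, 7)])
})

test_that("an all-zero linear predictor gives q = 0.5", {
  pp <- data.table::data.table(bin_index = rep(1:7, each = 40),
                               Y = rep(c(0L, 1L), 140))
  bl <- fit_baseline(pp)  # d/n = 0.5 in every bin -> beta = 0
  expect_equal(max(abs(bl$coef)), 0, tolerance = 1e-9)
  pr <- predict_hazard(bl, data.frame(bin_index = 1:7))
  expect_equal(pr$point, rep(0.5, 7), tolerance = 1e-9)
})

test_that("parametric fits are invariant to duplicating every row", {
  sim <- small_sim(mothers = 250)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  # unpenalized variant: the likelihood scales, so estimates are unchanged
  spec <- model_spec("ADD", re_survey = FALSE, re_country_bin = FALSE,
                     engine = "gam")
  f1 <- fit_full(pp, spec)
  f2 <- fit_full(rbind(pp, pp), spec)
  rows <- pp[sample(.N, 50)]
  expect_equal(predict_hazard(f1, rows)$point,
               predict_hazard(f2, rows)$point, tolerance = 1e-6)
})

test_that("predictions are invariant to rescaling a raw covariate", {
  sim <- small_sim(mothers = 250)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  spec <- model_spec("ADD", engine = "gam")
  f1 <- fit_full(pp, spec)
  pp2 <- data.table::copy(pp)[, sdi := sdi * 10]
  f2 <- fit_full(pp2, spec)
  rows <- pp[sample(.N, 80)]
  rows2 <- data.table::copy(rows)[, sdi := sdi * 10]
  expect_equal(predict_hazard(f1, rows)$point,
               predict_hazard(f2, rows2)$point, tolerance = 1e-6)
})

test_that("a simulated year trend is recovered with the right sign", {
  sim <- small_sim(mothers = 1500, countries = 2, trend_logit = -0.06,
                   frailty_sd = 0, survey_sd = 0, country_sd = 0)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  fit <- fit_full(pp, model_spec("ADD", engine = "gam"))
  rows <- pp[1][rep(1, 2)]
  rows[, birth_year := c(1990, 2005)]
  rows[, sdi := 0.4]
  pr <- predict_hazard(fit, rows)
  expect_gt(pr$point[1], pr$point[2])  # mortality declines over time
})

test_that("TREND predictions are calibrated to the saturated baseline", {
  # With flat simulated hazards the trend model nests the baseline; its
  # average predicted hazard per bin must reproduce the empirical death
  # fraction exactly (score equations of the unpenalized bin dummies), and
  # its fitted time variation must be small next to the hazard level.
  sim <- small_sim(mothers = 1200, countries = 2, trend_logit = 0,
                   sdi_effect = 0, frailty_sd = 0, survey_sd = 0,
                   country_sd = 0)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  bl <- suppressWarnings(fit_baseline(pp))
  fit <- fit_full(pp, model_spec("TREND", re_survey = FALSE,
                                 re_country_bin = FALSE, engine = "gam"))
  pr <- predict_hazard(fit, pp)
  avg <- data.table::data.table(bin_index = pp$bin_index, q = pr$point)
  avg <- avg[, list(q = mean(q)), by = "bin_index"][order(bin_index)]
  expect_equal(avg$q, bl$q, tolerance = 1e-6)
})

test_that("draws are reproducible, centred on the point prediction", {
  sim <- small_sim(mothers = 400)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  fit <- fit_full(pp, model_spec("ADD", engine = "gam"))
  rows <- pp[sample(.N, 30)]
  p1 <- predict_hazard(fit, rows, n_draws = 400, seed = 42)
  p2 <- predict_hazard(fit, rows, n_draws = 400, seed = 42)
  expect_identical(p1$draws, p2$draws)
  p3 <- predict_hazard(fit, rows, n_draws = 400, seed = 43)
  expect_false(identical(p1$draws, p3$draws))
  # draw mean of the linear predictor within 3 MC standard errors
  eta_draws <- stats::qlogis(p1$draws)
  eta_pt <- stats::qlogis(p1$point)
  mc_se <- apply(eta_draws, 1, stats::sd) / sqrt(ncol(eta_draws))
  expect_true(all(abs(rowMeans(eta_draws) - eta_pt) < 3 * mc_se + 1e-8))
})

test_that("unseen survey levels get zero point effect and seeded noise draws", {
  sim <- small_sim(mothers = 400)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  fit <- fit_full(pp, model_spec("ADD", engine = "gam"))
  rows <- pp[sample(.N, 10)]
  rows_new <- data.table::copy(rows)[, survey_id := "SVY_NEW"]
  rows_new[, country := "NOWHERE"]
  expect_silent(p <- predict_hazard(fit, rows_new, n_draws = 50, seed = 1))
  expect_true(all(p$point > 0 & p$point < 1))
  # same unseen level shares one effect across rows within a draw:
  # correlation of logit draws across two rows of the same new survey is
  # high only through shared effects; just check determinism here
  p2 <- predict_hazard(fit, rows_new, n_draws = 50, seed = 1)
  expect_identical(p$draws, p2$draws)
})

test_that("extrapolation beyond training covariates is flagged, not fatal", {
  sim <- small_sim(mothers = 300)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  fit <- fit_full(pp, model_spec("ADD", engine = "gam"))
  rows <- pp[1][rep(1, 2)]
  rows[2, birth_year := 2050]
  p <- predict_hazard(fit, rows)
  expect_equal(attr(p, "extrapolated"), c(FALSE, TRUE))
})

test_that("fitted models round-trip bit-exactly through the JSON container", {
  sim <- small_sim(mothers = 300)
  pp <- reshape_to_person_period(sim$children, sim$mothers, sim$sdi,
                                 quiet = TRUE)
  fit <- fit_full(pp, model_spec("ADD", engine = "gam"))
  path <- withr::local_tempfile(fileext = ".json")
  write_dtsa_model(fit, path)
  fit2 <- read_dtsa_model(path)
  expect_identical(stats::coef(fit$gam), stats::coef(fit2$gam))
  rows <- pp[sample(.N, 40)]
  expect_identical(predict_hazard(fit, rows)$point,
                   predict_hazard(fit2, rows)$point)
  expect_identical(predict_hazard(fit, rows, n_draws = 20, seed = 9)$draws,
                   predict_hazard(fit2, rows, n_draws = 20, seed = 9)$draws)
})
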
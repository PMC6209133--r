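test_that("survival to entry matches the loop oracle", {
  expect_equal(survival_to_entry(rep(0, 5)), rep(1, 5))
  expect_equal(survival_to_entry(c(0.1, 0.1, 0.1)), c(1, 0.9, 0.81))
  set.seed(4)
  for (i in 1:20) {
    q <- stats::runif(7)
    expect_equal(survival_to_entry(q), oracle_survival(q), tolerance = 1e-12)
  }
  # matrix version agrees with the vector version column-wise
  qm <- matrix(stats::runif(21), nrow = 7)
  sm <- sbhmort:::survival_to_entry_mat(qm)
  for (j in 1:3) expect_equal(sm[, j], survival_to_entry(qm[, j]),
                              tolerance = 1e-12)
})

fake_hyp <- function(pob, ceb, mother_id = "m1", birth_year = 2008,
                     country = "X") {
  data.table::data.table(
    mother_id = mother_id, survey_id = "S1", country = country,
    region = "all", survey_year = 2010, survey_weight = 1,
    ceb = ceb, cd = 0, cd_over_ceb = 0, t = 2010 - birth_year,
    birth_year = birth_year, mother_age_at_birth = 28,
    ceb_at_birth = 1, sdi = 0.5, pob = pob)
}

test_that("EEB follows POB * CEB * survival-to-entry", {
  hyp <- fake_hyp(pob = 0.5, ceb = 2)
  q <- c(0.1, rep(0, 6))
  pred <- structure(list(point = q, draws = NULL),
                    class = "hazard_prediction")
  eeb <- compute_eeb(hyp, pred)$eeb
  expect_equal(eeb$eeb[1], 1.0)   # bin 1 gets full weight POB * CEB
  expect_equal(eeb$eeb[2], 0.9)
  expect_equal(eeb$eeb[7], 0.9)
  # POB = 0 kills all weight
  eeb0 <- compute_eeb(fake_hyp(pob = 0, ceb = 3), pred)$eeb
  expect_true(all(eeb0$eeb == 0))
  # zero hazards give constant weight
  predz <- structure(list(point = rep(0, 7), draws = NULL),
                     class = "hazard_prediction")
  eebz <- compute_eeb(fake_hyp(pob = 0.25, ceb = 4), predz)$eeb
  expect_true(all(abs(eebz$eeb - 1) < 1e-12))
})

test_that("aggregation is the EEB-weighted mean of hazards", {
  hyp <- data.table::rbindlist(list(fake_hyp(0.5, 2, "m1"),
                                    fake_hyp(0.5, 2, "m2")))
  # identical single bin structure: use bin-1 hazards 0.1 and 0.3
  pred <- structure(list(point = as.vector(rbind(c(0.1, 0.3),
                                                 matrix(0, 6, 2))),
                         draws = NULL), class = "hazard_prediction")
  eeb <- compute_eeb(hyp, pred)
  tr <- aggregate_trends(eeb, grouping = "country")
  expect_equal(tr$estimates[bin_index == 1, q], 0.2)  # equal weights
  # unequal EEB: weight 3 vs 1 via CEB
  hyp2 <- data.table::rbindlist(list(fake_hyp(0.5, 6, "m1"),
                                     fake_hyp(0.5, 2, "m2")))
  eeb2 <- compute_eeb(hyp2, pred)
  tr2 <- aggregate_trends(eeb2, grouping = "country")
  expect_equal(tr2$estimates[bin_index == 1, q], 0.15)
  # single mother, single child: q passes through
  tr1 <- aggregate_trends(compute_eeb(fake_hyp(0.5, 2), structure(
    list(point = c(0.07, rep(0.01, 6)), draws = NULL),
    class = "hazard_prediction")), grouping = "country")
  expect_equal(tr1$estimates[bin_index == 1, q], 0.07)
})

test_that("constant hazards aggregate to the constant for any weights", {
  set.seed(12)
  hyp <- data.table::rbindlist(lapply(1:10, function(i) {
    fake_hyp(stats::runif(1), sample(1:6, 1), sprintf("m%d", i))
  }))
  pred <- structure(list(point = rep(0.04, 7 * 10), draws = NULL),
                    class = "hazard_prediction")
  tr <- aggregate_trends(compute_eeb(hyp, pred), grouping = "country")
  expect_true(all(abs(tr$estimates$q - 0.04) < 1e-12))
})

test_that("survey weights multiply into both summands", {
  hyp <- data.table::rbindlist(list(fake_hyp(0.5, 2, "m1"),
                                    fake_hyp(0.5, 2, "m2")))
  hyp[mother_id == "m1", survey_weight := 3]
  pred <- structure(list(point = as.vector(rbind(c(0.1, 0.3),
                                                 matrix(0, 6, 2))),
                         draws = NULL), class = "hazard_prediction")
  eeb <- compute_eeb(hyp, pred)
  tr_w <- aggregate_trends(eeb, grouping = "country",
                           use_survey_weights = TRUE)
  expect_equal(tr_w$estimates[bin_index == 1, q], (3 * 0.1 + 0.3) / 4)
  tr_u <- aggregate_trends(eeb, grouping = "country",
                           use_survey_weights = FALSE)
  expect_equal(tr_u$estimates[bin_index == 1, q], 0.2)
})

test_that("bin combination multiplies conditional survival", {
  hyp <- fake_hyp(0.5, 2)
  q <- c(0.03, 0.015, 0.013, 0.01, 0.008, 0.006, 0.004)
  pred <- structure(list(point = q, draws = NULL),
                    class = "hazard_prediction")
  tr <- aggregate_trends(compute_eeb(hyp, pred), grouping = "country")
  q1 <- combine_bins(tr, "1q0")
  expect_equal(q1$q, 1 - 0.97 * 0.985 * 0.987, tolerance = 1e-12)
  q5 <- combine_bins(tr, "5q0")
  expect_equal(q5$q, oracle_combine(q), tolerance = 1e-12)
  # custom contiguous set
  q2 <- combine_bins(tr, 1:4)
  expect_equal(q2$q, oracle_combine(q[1:4]), tolerance = 1e-12)
  # degenerate cases
  expect_error(combine_bins(tr, c(2, 3)), "contiguous")
  expect_error(combine_bins(tr, c(1, 3)), "contiguous")
})

test_that("combination identities hold at the boundaries", {
  hyp <- fake_hyp(1, 1)
  mk <- function(q) aggregate_trends(compute_eeb(hyp, structure(
    list(point = q, draws = NULL), class = "hazard_prediction")),
    grouping = "country")
  expect_equal(combine_bins(mk(rep(0, 7)), "5q0")$q, 0)
  expect_equal(combine_bins(mk(c(1, rep(0, 6))), "5q0")$q, 1)
})

test_that("uncertainty summaries use mean and type-7 quantiles", {
  draws <- (1:100) / 1000
  s <- summarize_uncertainty(draws)
  expect_equal(s$q, mean(draws))
  expect_equal(s$lwr, stats::quantile(draws, 0.025, names = FALSE, type = 7))
  expect_equal(s$upr, stats::quantile(draws, 0.975, names = FALSE, type = 7))
  # all draws identical: bounds collapse onto the point
  s2 <- summarize_uncertainty(rep(0.042, 50))
  expect_equal(s2$q, 0.042)
  expect_equal(s2$lwr, 0.042)
  expect_equal(s2$upr, 0.042)
  # bounds contain the point
  set.seed(3)
  d <- stats::rbeta(500, 2, 50)
  s3 <- summarize_uncertainty(d)
  expect_true(s3$lwr <= s3$q && s3$q <= s3$upr)
})
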
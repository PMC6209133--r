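#' Specify a discrete-time survival additive model
#'
#' The model variants mirror a ladder of specifications for the discrete
#' hazard of death of child *i* of mother *m* in age bin *a*:
#' \deqn{logit(q_{m,i,a}) = \sum_a I_a \beta_a + \sum_a g_{1,a}(yr, SDI) I_a
#'   + g_2(CD/CEB, CEB_{at birth}, MothAge) + \nu_{survey} + \eta_{country,a}}
#' \describe{
#'   \item{FULL}{per-bin thin plate smooth of (birth year, SDI) plus a joint
#'     smooth of the mother-level covariates, plus both random intercepts.}
#'   \item{INT}{same covariates with smooth interactions replaced by linear
#'     interaction terms.}
#'   \item{ADD}{all covariates entered additively and untransformed.}
#'   \item{TREND}{only the per-bin (year, SDI) smooth; no individual-level
#'     covariates.}
#'   \item{INDIV}{only the individual-level covariate smooth; no year-SDI
#'     trend.}
#' }
#' Random intercepts are independent normals per survey (`nu`) and per
#' (country, age bin) (`eta`).
#'
#' @param variant Model variant, one of `"FULL"`, `"INT"`, `"ADD"`,
#'   `"TREND"`, `"INDIV"`.
#' @param k_trend Basis dimension of each per-bin (year, SDI) smooth.
#' @param k_indiv Basis dimension of the joint mother-covariate smooth.
#' @param re_survey,re_country_bin Include the survey / country-by-bin
#'   random intercepts (automatically disabled when fewer than two levels
#'   are available).
#' @param engine `"auto"` (bam with discrete fitting for large tables, gam
#'   otherwise), `"bam"`, or `"gam"`. Penalties are selected by (fast)
#'   restricted maximum likelihood in either case.
#' @param q_floor Numerical floor/ceiling applied to predicted hazards.
#' @return A list of class `dtsa_spec`.
#' @export
model_spec <- function(variant = c("FULL", "INT", "ADD", "TREND", "INDIV"),
                       k_trend = 10, k_indiv = 25,
                       re_survey = TRUE, re_country_bin = TRUE,
                       engine = c("auto", "bam", "gam"),
                       q_floor = 1e-12) {
  structure(list(variant = match.arg(variant), k_trend = k_trend,
                 k_indiv = k_indiv, re_survey = re_survey,
                 re_country_bin = re_country_bin,
                 engine = match.arg(engine), q_floor = q_floor),
            class = "dtsa_spec")
}

# Covariates demanded by each variant (raw column names in person-period
# data). The bin dummies are always present.
variant_covariates <- function(variant) {
  trend <- c("birth_year", "sdi")
  indiv <- c("cd_over_ceb", "ceb_at_birth", "mother_age_at_birth")
  switch(variant,
         FULL = c(trend, indiv), INT = c(trend, indiv),
         ADD = c(trend, indiv), TREND = trend, INDIV = indiv)
}

#' Fit the saturated (no-covariate) baseline hazard model
#'
#' Fits the intercept-free logistic regression of the death indicator on
#' age-bin dummies, the saturated discrete-hazard model whose inverse-logit
#' coefficients equal the empirical per-bin death fractions `d_a / n_a`.
#'
#' @param person_period Person-period table from
#'   [reshape_to_person_period()].
#' @param scheme The [age_bin_scheme()] the table was built with.
#' @return A `dtsa_fit` with elements `q` (per-bin hazard, `NA` for bins
#'   with no entrants), `counts`, `coef`, `vcov`, and a `divergent` flag per
#'   bin (`TRUE` where `d = 0` or `d = n`, so the logistic coefficient is
#'   unbounded and `q` is reported as the boundary value).
#' @export
fit_baseline <- function(person_period, scheme = age_bin_scheme()) {
  pp <- data.table::as.data.table(person_period)
  assert_cols(pp, c("bin_index", "Y"), "person-period table")
  A <- n_bins(scheme)
  counts <- pp[, list(d = sum(Y), n = .N), by = "bin_index"]
  counts <- merge(data.table::data.table(bin_index = seq_len(A)), counts,
                  by = "bin_index", all.x = TRUE)
  counts[is.na(n), c("d", "n") := list(0L, 0L)]
  obs <- counts[n > 0]
  if (nrow(obs) == 0) stop("fit_baseline: no person-period rows")
  if (nrow(obs) > 1) {
    fit <- stats::glm(cbind(d, n - d) ~ 0 + factor(bin_index, levels = obs$bin_index),
                      family = stats::binomial(), data = obs,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
  } else {
    # degenerate single-bin design: closed-form saturated MLE
    p <- obs$d / obs$n
    beta <- logit(min(max(p, 1e-12), 1 - 1e-12))
    vc <- matrix(1 / max(obs$n * p * (1 - p), .Machine$double.eps), 1, 1)
  }
  q <- rep(NA_real_, A)
  q[obs$bin_index] <- invlogit(beta)
  divergent <- counts$n > 0 & (counts$d == 0L | counts$d == counts$n)
  q[counts$n > 0 & counts$d == 0L] <- 0
  q[counts$n > 0 & counts$d == counts$n] <- 1
  structure(list(variant = "BASELINE", scheme = scheme, q = q,
                 counts = counts[], coef = beta, vcov = vc,
                 divergent = divergent, q_floor = 1e-12),
            class = "dtsa_fit")
}

scale_covariates <- function(dt, covs, scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- lapply(covs, function(v) {
      x <- dt[[v]]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        warning(sprintf("covariate '%s' is constant; scaling by 1", v))
        s <- 1
      }
      list(center = mean(x), scale = s)
    })
    names(scaling) <- covs
  }
  for (v in covs) {
    dt[, paste0(v, "_s") := (get(v) - scaling[[v]]$center) / scaling[[v]]$scale]
  }
  scaling
}

variant_formula <- function(spec, re_survey, re_country_bin) {
  trend_s <- sprintf("s(birth_year_s, sdi_s, by = bin_f, bs = \"tp\", k = %d)",
                     spec$k_trend)
  indiv_s <- sprintf("s(cd_over_ceb_s, ceb_at_birth_s, mother_age_at_birth_s, bs = \"tp\", k = %d)",
                     spec$k_indiv)
  terms <- switch(spec$variant,
    FULL  = c(trend_s, indiv_s),
    TREND = trend_s,
    INDIV = indiv_s,
    INT   = c("bin_f:birth_year_s", "bin_f:sdi_s", "bin_f:birth_year_s:sdi_s",
              "cd_over_ceb_s * ceb_at_birth_s * mother_age_at_birth_s"),
    ADD   = c("birth_year_s", "sdi_s", "cd_over_ceb_s", "ceb_at_birth_s",
              "mother_age_at_birth_s"))
  if (re_survey) terms <- c(terms, "s(survey_f, bs = \"re\")")
  if (re_country_bin) terms <- c(terms, "s(country_f, bin_f, bs = \"re\")")
  stats::as.formula(paste("Y ~ 0 + bin_f +", paste(terms, collapse = " + ")))
}

#' Fit the penalized additive discrete-time survival model
#'
#' Fits the specified model variant to person-period data via `mgcv`
#' (restricted maximum likelihood penalty selection; `bam` with discrete
#' fitting methods for large tables). Covariates are centred and scaled by
#' their standard deviations before basis construction, and the constants
#' are stored for prediction. Fitting is intended to be run separately per
#' region when a region stratification is in use; this function fits
#' whatever rows it is given and records `region` as a label.
#'
#' @inheritParams fit_baseline
#' @param spec A [model_spec()].
#' @param region Optional label of the training region.
#' @return A `dtsa_fit` containing the mgcv fit, the scaling constants, the
#'   random-effect standard deviations, training factor levels and
#'   covariate ranges.
#' @export
fit_full <- function(person_period, spec = model_spec(),
                     scheme = age_bin_scheme(), region = NULL) {
  stopifnot(inherits(spec, "dtsa_spec"))
  pp <- data.table::as.data.table(person_period)
  covs <- variant_covariates(spec$variant)
  assert_cols(pp, c("bin_index", "Y", "survey_id", "country", covs),
              "person-period table")
  ok <- stats::complete.cases(pp[, c(covs), with = FALSE])
  if (!all(ok)) {
    message(sprintf("fit_full: dropping %d row(s) with missing covariates",
                    sum(!ok)))
    pp <- pp[ok]
  }
  dat <- pp[, c("Y", "bin_index", "survey_id", "country", covs), with = FALSE]
  dat[, "bin_f" := factor(scheme$label[bin_index], levels = scheme$label)]
  dat[, "survey_f" := factor(survey_id)]
  dat[, "country_f" := factor(country)]
  scaling <- scale_covariates(dat, covs)

  re_survey <- spec$re_survey && nlevels(dat$survey_f) >= 2
  re_country_bin <- spec$re_country_bin && nlevels(dat$country_f) >= 2
  if (spec$re_survey && !re_survey) {
    message("fit_full: < 2 surveys; survey random intercept disabled")
  }
  if (spec$re_country_bin && !re_country_bin) {
    message("fit_full: < 2 countries; country-by-bin random intercept disabled")
  }

  form <- variant_formula(spec, re_survey, re_country_bin)
  use_bam <- spec$engine == "bam" ||
    (spec$engine == "auto" && nrow(dat) > 50000)
  fit <- if (use_bam) {
    mgcv::bam(form, family = stats::binomial(), data = dat,
              method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, family = stats::binomial(), data = dat, method = "REML")
  }
  if (!fit$converged) stop("fit_full: model did not converge; ",
                           "inspect covariates or reduce basis dimensions")

  # Random-effect standard deviations, for simulating effects of unseen
  # survey / country levels at prediction time. REML variance components
  # collapse toward zero when only a handful of levels are available, so
  # the empirical spread of the fitted effects serves as a lower bound:
  # understating this variance would understate uncertainty for every new
  # survey the model is applied to.
  vc <- tryCatch({
    junk <- utils::capture.output(v <- mgcv::gam.vcomp(fit, rescale = TRUE))
    v
  }, error = function(e) NULL)
  sd_of <- function(tag) {
    if (is.null(vc)) return(NA_real_)
    i <- grep(tag, rownames(vc), fixed = TRUE)
    if (length(i) != 1) NA_real_ else unname(vc[i, "std.dev"])
  }
  emp_sd_of <- function(tag) {
    for (sm in fit$smooth) {
      if (sm$label == tag) {
        return(stats::sd(stats::coef(fit)[sm$first.para:sm$last.para]))
      }
    }
    NA_real_
  }
  pool_sd <- function(reml, emp) max(reml, emp, 0, na.rm = TRUE)
  sigma_nu <- if (re_survey) {
    pool_sd(sd_of("s(survey_f)"), emp_sd_of("s(survey_f)"))
  } else 0
  sigma_eta <- if (re_country_bin) {
    pool_sd(sd_of("s(country_f,bin_f)"), emp_sd_of("s(country_f,bin_f)"))
  } else 0

  ranges <- lapply(covs, function(v) range(pp[[v]]))
  names(ranges) <- covs

  structure(list(
    variant = spec$variant, spec = spec, scheme = scheme, gam = fit,
    scaling = scaling, region = region,
    sigma_nu = sigma_nu, sigma_eta = sigma_eta,
    re_survey = re_survey, re_country_bin = re_country_bin,
    survey_levels = levels(dat$survey_f), country_levels = levels(dat$country_f),
    cov_ranges = ranges, n_rows = nrow(dat), q_floor = spec$q_floor),
    class = "dtsa_fit")
}

#' @export
print.dtsa_fit <- function(x, ...) {
  if (x$variant == "BASELINE") {
    cat("Saturated baseline discrete-hazard fit\n")
    print(data.table::data.table(bin = x$scheme$label, q = x$q))
  } else {
    cat(sprintf("DTSA additive fit, variant %s: %d person-period rows, %d surveys, %d countries\n",
                x$variant, x$n_rows, length(x$survey_levels),
                length(x$country_levels)))
    cat(sprintf("  random-effect SDs: survey %.4f, country x bin %.4f\n",
                x$sigma_nu, x$sigma_eta))
  }
  invisible(x)
}

# --- prediction ------------------------------------------------------------

# Column ranges of the random-effect smooth blocks in the coefficient
# vector, so unseen-level rows can have those columns zeroed.
re_para_ranges <- function(gamfit) {
  out <- list()
  for (sm in gamfit$smooth) {
    if (inherits(sm, "random.effect")) {
      out[[sm$label]] <- sm$first.para:sm$last.para
    }
  }
  out
}

map_levels <- function(x, train_levels) {
  x <- as.character(x)
  unseen <- !x %in% train_levels
  mapped <- x
  mapped[unseen] <- train_levels[1]
  list(f = factor(mapped, levels = train_levels), unseen = unseen,
       unseen_values = x)
}

# Build the linear-predictor matrix for new rows, with random-effect
# columns zeroed for rows whose survey / country level was not in training.
dtsa_lpmatrix <- function(fit, rows) {
  covs <- variant_covariates(fit$variant)
  nd <- data.table::as.data.table(rows)
  assert_cols(nd, c("bin_index", "survey_id", "country", covs),
              "prediction rows")
  nd <- nd[, c("bin_index", "survey_id", "country", covs), with = FALSE]
  nd[, "bin_f" := factor(fit$scheme$label[bin_index],
                         levels = fit$scheme$label)]
  scale_covariates(nd, covs, fit$scaling)
  svy <- map_levels(nd$survey_id, fit$survey_levels)
  ctr <- map_levels(nd$country, fit$country_levels)
  nd[, "survey_f" := svy$f]
  nd[, "country_f" := ctr$f]
  X <- stats::predict(fit$gam, newdata = nd, type = "lpmatrix")
  para <- re_para_ranges(fit$gam)
  for (lab in names(para)) {
    mask <- if (grepl("survey_f", lab, fixed = TRUE)) svy$unseen else ctr$unseen
    if (any(mask)) X[mask, para[[lab]]] <- 0
  }
  extrap <- rep(FALSE, nrow(nd))
  for (v in covs) {
    r <- fit$cov_ranges[[v]]
    extrap <- extrap | nd[[v]] < r[1] | nd[[v]] > r[2]
  }
  list(X = X, svy = svy, ctr = ctr, extrapolated = extrap,
       bin_label = as.character(nd$bin_f))
}

# Draw coefficient vectors and unseen-level random effects once, so the
# same parameter draws can be applied across prediction chunks.
prepare_draws <- function(fit, n_draws, new_surveys = character(),
                          new_country_bins = character(), seed = NULL) {
  if (n_draws <= 0) return(NULL)
  # Draw from the smoothing-parameter-uncertainty-corrected covariance when
  # the backend provides it; otherwise the conditional Bayesian covariance.
  V <- fit$gam$Vc %||% fit$gam$Vp
  with_seed(seed, {
    beta <- mgcv::rmvn(n_draws, stats::coef(fit$gam), V)
    if (n_draws == 1) beta <- matrix(beta, nrow = 1)
    nu <- if (length(new_surveys) && fit$re_survey && is.finite(fit$sigma_nu)) {
      m <- matrix(stats::rnorm(length(new_surveys) * n_draws, 0, fit$sigma_nu),
                  nrow = length(new_surveys),
                  dimnames = list(new_surveys, NULL))
      m
    } else NULL
    eta <- if (length(new_country_bins) && fit$re_country_bin &&
               is.finite(fit$sigma_eta)) {
      matrix(stats::rnorm(length(new_country_bins) * n_draws, 0,
                          fit$sigma_eta),
             nrow = length(new_country_bins),
             dimnames = list(new_country_bins, NULL))
    } else NULL
    list(beta = beta, nu = nu, eta = eta, n_draws = n_draws)
  })
}

#' Predict per-bin hazards from a fitted DTSA model
#'
#' Computes point hazard predictions (inverse-logit of the linear predictor
#' with fitted random intercepts) and, optionally, hazards under `n_draws`
#' multivariate normal draws from the covariance matrix of the fitted
#' parameters (including fitted random effects). Rows whose survey or
#' country level was not seen in training get a point random effect of 0,
#' and per draw an independent normal effect with the estimated
#' random-effect variance, shared across all rows of the same unseen level.
#' Covariate values outside the training range are predicted (never an
#' error) and flagged in attribute `"extrapolated"`.
#'
#' @param fit A `dtsa_fit` from [fit_full()] or [fit_baseline()].
#' @param rows Prediction rows carrying `bin_index`, `survey_id`, `country`,
#'   and the covariates the fitted variant uses ([fit_baseline()] fits need
#'   only `bin_index`).
#' @param n_draws Number of parameter draws (0 for point prediction only).
#' @param seed Integer seed making the draws reproducible.
#' @param draws Optionally, a pre-computed draw set from an internal call;
#'   overrides `n_draws`/`seed`.
#' @return A list of class `hazard_prediction` with elements `point`
#'   (numeric vector on `(0, 1)`) and `draws` (matrix rows x n_draws, or
#'   `NULL`).
#' @export
predict_hazard <- function(fit, rows, n_draws = 0, seed = NULL, draws = NULL) {
  stopifnot(inherits(fit, "dtsa_fit"))
  rows <- data.table::as.data.table(rows)
  if (fit$variant == "BASELINE") {
    assert_cols(rows, "bin_index", "prediction rows")
    point <- clamp_prob(fit$q[rows$bin_index], fit$q_floor)
    dr <- NULL
    if (n_draws > 0) {
      obs_bins <- fit$counts$bin_index[fit$counts$n > 0 & !fit$divergent]
      beta <- with_seed(seed, mgcv::rmvn(n_draws, fit$coef, fit$vcov))
      if (n_draws == 1) beta <- matrix(beta, nrow = 1)
      qd <- matrix(rep(point, n_draws), ncol = n_draws)
      pos <- match(rows$bin_index, obs_bins)
      has <- !is.na(pos)
      qd[has, ] <- clamp_prob(invlogit(t(beta)[pos[has], , drop = FALSE]),
                              fit$q_floor)
      dr <- qd
    }
    out <- list(point = point, draws = dr)
    class(out) <- "hazard_prediction"
    attr(out, "extrapolated") <- rep(FALSE, nrow(rows))
    return(out)
  }

  lp <- dtsa_lpmatrix(fit, rows)
  beta_hat <- stats::coef(fit$gam)
  eta_point <- drop(lp$X %*% beta_hat)
  point <- clamp_prob(invlogit(eta_point), fit$q_floor)

  dmat <- NULL
  if (is.null(draws) && n_draws > 0) {
    new_surveys <- unique(lp$svy$unseen_values[lp$svy$unseen])
    new_cb <- unique(paste(lp$ctr$unseen_values[lp$ctr$unseen],
                           lp$bin_label[lp$ctr$unseen], sep = "\r"))
    draws <- prepare_draws(fit, n_draws, new_surveys, new_cb, seed = seed)
  }
  if (!is.null(draws)) {
    eta_d <- lp$X %*% t(draws$beta)
    if (!is.null(draws$nu) && any(lp$svy$unseen)) {
      i <- which(lp$svy$unseen)
      key <- lp$svy$unseen_values[i]
      has <- key %in% rownames(draws$nu)
      eta_d[i[has], ] <- eta_d[i[has], , drop = FALSE] +
        draws$nu[key[has], , drop = FALSE]
    }
    if (!is.null(draws$eta) && any(lp$ctr$unseen)) {
      i <- which(lp$ctr$unseen)
      key <- paste(lp$ctr$unseen_values[i], lp$bin_label[i], sep = "\r")
      has <- key %in% rownames(draws$eta)
      eta_d[i[has], ] <- eta_d[i[has], , drop = FALSE] +
        draws$eta[key[has], , drop = FALSE]
    }
    dmat <- clamp_prob(invlogit(eta_d), fit$q_floor)
  }
  out <- list(point = point, draws = dmat)
  class(out) <- "hazard_prediction"
  attr(out, "extrapolated") <- lp$extrapolated
  out
}

# --- serialization ---------------------------------------------------------

#' Serialize a fitted DTSA model to a JSON container
#'
#' Writes a self-describing JSON file holding the model variant, scaling
#' constants, random-effect standard deviations, coefficient vector, and an
#' encoded payload with the complete fit object, so the model round-trips
#' bit-exactly. The readable fields document the fit; the payload
#' reconstructs it.
#'
#' @param fit A `dtsa_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dtsa_model <- function(fit, path) {
  stopifnot(inherits(fit, "dtsa_fit"))
  coefs <- if (fit$variant == "BASELINE") fit$coef else stats::coef(fit$gam)
  obj <- list(
    format = "sbhmort-dtsa", format_version = 1L,
    package_version = as.character(utils::packageVersion("sbhmort")),
    variant = fit$variant,
    scaling = fit$scaling %||% NULL,
    sigma_nu = fit$sigma_nu %||% NULL,
    sigma_eta = fit$sigma_eta %||% NULL,
    coefficients = as.list(coefs),
    payload = jsonlite::base64_enc(serialize(fit, NULL))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dtsa_model
#' @export
read_dtsa_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "sbhmort-dtsa")) {
    stop("not a serialized DTSA model: ", path)
  }
  fit <- unserialize(jsonlite::base64_dec(obj$payload))
  stopifnot(inherits(fit, "dtsa_fit"))
  fit
}
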
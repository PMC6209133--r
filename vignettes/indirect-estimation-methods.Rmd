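---
title: "Indirect age-specific child mortality estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect age-specific child mortality estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Summary birth histories (SBH) ask each woman only how many children she
has ever borne (CEB), how many have died (CD), and her age. They are
collected in most censuses and many household surveys, so they represent
by far the largest body of information on child survival in countries
without complete vital registration — but they say nothing explicit about
*when* children were born or died. Complete birth histories (CBH), which
record each child's birth date and age at death, allow mortality to be
tabulated directly by age and calendar year, but are far scarcer.

`sbhmort` converts SBH data into annual age-specific mortality trends by
exploiting surveys in which both instruments were collected. A hazard
model is trained on CBH data using only predictors that an SBH also
provides; the fitted model is then applied to SBH-only data through the
device of *hypothetical children*.

## The discrete-time survival model

Each child's life up to age five is cut into seven age bins chosen to
match how survey ages at death are reported (days under one month, months
under two years, years after): NN `[0, 29)` days, PNN1 `[29, 183)`, PNN2
`[183, 365)`, and single-year bins `1yr` to `4yr` up to 1,825 days.
Intervals are half-open; a death at an exact boundary belongs to the
later bin. The CBH is reshaped so that every row is one (child, bin)
exposure with a death indicator; a living child's partially entered bin
is censored at entry and contributes no row. With bins indexed by $a$,
the conditional probability of death $q_a$ (the discrete hazard) is
modelled as

$$\operatorname{logit}(q_{m,i,a}) = \sum_a I_a \beta_a
  + \sum_a g_{1,a}(\mathrm{yr}_i, \mathrm{SDI}_{c,\mathrm{yr}}) I_a
  + g_2\!\left(\tfrac{CD_m}{CEB_m}, CEB_{m,\mathrm{yr}},
               \mathrm{MothAge}_{m,\mathrm{yr}}\right)
  + \nu_{\mathrm{survey}} + \eta_{\mathrm{country},a},$$

with no global intercept, so that $\operatorname{logit}^{-1}(\beta_a)$ is
the baseline hazard of bin $a$. The $g$ terms are thin plate regression
spline smooths; $g_{1,a}$ has a separate smooth per age bin so that the
secular trend, and its modulation by the Socio-demographic Index (SDI, a
0–1 development composite), can differ by age. $g_2$ carries the
mother-level information an SBH provides: her lifetime dead-to-born
ratio, the number of children she had already borne when this child was
born, and her age at the birth. $\nu$ and $\eta$ are independent normal
random intercepts per survey and per country-by-bin. Fitting uses
restricted maximum likelihood through `mgcv` (`bam` with discrete
methods for large tables), with covariates centred and scaled before
basis construction. A ladder of simpler variants (`INT`, `ADD`, `TREND`,
`INDIV`) replaces the smooths by linear interactions, drops interactions,
or drops either covariate block, and is useful for ablation.

Prediction uncertainty comes from multivariate normal draws of the fitted
coefficient vector. The draw covariance includes the smoothing-parameter
uncertainty correction where the backend provides it; this is a
documented choice, since one could also draw conditionally on the fitted
penalties. For survey or country levels unseen in training, the point
prediction sets the random effect to zero and each draw adds an
independent normal effect, shared by all rows of that level. Because REML
variance components collapse toward zero when only a handful of levels is
available, the standard deviation used for unseen levels is the larger of
the REML estimate and the empirical spread of the fitted effects — a
deliberately conservative floor.

## From per-child hazards to population trends

For each SBH respondent the package enumerates one hypothetical child per
calendar year from the survey year back to the year she was 12. Each
hypothetical child gets covariates from the mother's history, an imputed
CEB-at-birth, and a probability of actually having existed (POB), looked
up in empirical birth-timing distributions tabulated from CBH data by
region, maternal age at survey, CEB class (0–7, 8+) and years before the
survey. Missing cells back off by pooling CEB classes, then ages within
one year, then regions. The CEB-at-birth imputation is one plus the
mother's CEB times the POB mass at years earlier than the birth, capped
at her CEB; it is isolated in one function (`impute_ceb_at_birth`)
precisely because other concretizations are conceivable.

Each (hypothetical child, bin) then receives the weight

$$EEB_{m,a,\mathrm{yr}} = POB_{m,\mathrm{yr}} \times CEB_m \times
  \hat S_{m,a,\mathrm{yr}},$$

the expected number of real children entering the bin that this
hypothetical child represents. $\hat S$ is survival to bin *entry*
($\hat S_1 = 1$), the only convention under which the quantity counts
children entering the bin; descriptions of $\hat S$ as "survival until
bin $a$" are ambiguous between entry and exit, and entry is used
throughout. Population trends are EEB-weighted means,

$$\hat q_{a,\mathrm{yr}} = \frac{\sum_m \hat q\, EEB}{\sum_m EEB},$$

whose numerator and denominator are interpretable as expected deaths and
expected entrants. Survey weights multiply both summands when enabled.
Aggregation can target any grouping of mothers (country, admin-1 area, a
whole pooled population). Wider measures such as infant mortality (1q0)
and under-five mortality (5q0) combine bins as independent conditional
probabilities, $1 - \prod_a (1 - q_a)$, per draw. Intervals are empirical
2.5%/97.5% quantiles over draws under the linear-interpolation (type 7)
convention, and the reported point estimate is the mean of the draws when
draws are present (so point and interval derive from one sample);
otherwise it is the plug-in estimate. The difference is small because
the aggregated hazard is nearly linear in the coefficients over the
posterior spread.

## Validation machinery

Direct tabulation of CBH data (children entering and dying in each bin,
by group and birth year, optionally pooled into 5-year periods for sparse
subnational work) provides the validation target. Because single-year
direct estimates are noisy realizations of the underlying hazard,
validation series can be loess-smoothed over year (span 0.85, local
linear, tricube weights, no robustness iterations) before scoring.
Five metrics, each weighted by the validation sample sizes, summarize
agreement: mean error, standard deviation of errors (weighted
consistently with the rest; an unweighted convention is equally
defensible), median relative error, median absolute percentage error, and
$R^2$ computed as one minus the weighted residual sum of squares over
the weighted variance of the validation values. The weighted median is
the smallest value whose cumulative weight reaches half the total; with
equal weights this is the lower sample median. Cells with zero validation
values are excluded from the two relative metrics and counted. Pairing of
indirect and direct series keeps estimates within 15 years of their
survey and years from 1990 on, the standard comparison window.

## The synthetic population generator

All tests run against `simulate_population()`, which generates paired
CBH/SBH data with known truth. Its hazard model is logit-additive —
per-bin baselines, a linear year trend, a linear SDI effect, country and
survey intercepts, and a mother-level frailty — deliberately the same
structural family as the fitted model so that recovery tests are well
posed, with a `misspecified` switch that adds an age-varying frailty
loading the fitted model cannot represent. Defaults are chosen to mimic
survey-era high-mortality settings: baseline hazards from about 0.031
(neonatal) to 0.003 (age four) at the 2000 reference year and SDI 0.5, a
−0.03 logit year trend plus a −2.5 logit SDI effect (together roughly a
4%/year hazard decline as SDI rises), frailty SD 0.25, survey SD 0.05 and
country SD 0.10 on the logit scale, and a hump-shaped fertility schedule
peaking at age 23 that yields completed family sizes around four
children. Ages are resolved at whole calendar years: a death can only be
observed in a bin fully completed before the survey, consistently with
the person-period censoring convention, and coded ages at death are drawn
uniformly within the death bin in the survey's days/months/years
convention, which decodes back to the same bin exactly.

The ground truth reported per (country, year, bin) is the
entrant-weighted marginal hazard, integrating the frailty numerically
with survivor selection, with the realized country intercept included and
survey effects at their mean of zero.

What the generator does *not* emulate matters for interpreting green
tests: real birth-date heaping and misreporting, recall-driven omission
of early deaths, fertility correlated with mortality risk, sex
differences, clustered sampling designs (only a single weight column is
carried), and non-stationary birth-timing distributions. Passing recovery
tests show the machinery is correct and the method works when its
assumptions hold, not that real-survey biases are overcome.

## Numerical and design choices

* Age-unit conversion is centralized: months to days by `round(30.44 m)`,
  years by `round(365.25 y)`.
* Predicted hazards are clamped to `[1e-12, 1 - 1e-12]` so survival
  products and logits stay finite.
* The trend smooth dimension defaults to `k_trend = 10`; analyses in this
  package's own tests and acceptance script use `k_trend = 6` because at
  desk-scale training sizes (tens of thousands of children per region)
  the per-bin death counts support only a few effective degrees of
  freedom, and smaller bases extrapolate the secular trend more stably
  over the out-of-sample projection years. The mother-covariate smooth
  uses a rank-25 three-dimensional thin plate basis; a tensor
  factorization would be an equally defensible structure.
* Fitting switches from `gam(REML)` to `bam(fREML, discrete = TRUE)`
  above 50,000 person-period rows.
* Region stratification is the caller's responsibility (`fit_full` fits
  the rows it is given); the synthetic default is a single pooled region.
* Prediction at scale is chunked over mothers with a fixed memory budget
  for draw matrices; parameter draws are taken once and shared across
  chunks, so results are chunk-invariant.
* `ceb_at_birth` in training counts all of the mother's births with birth
  year not after the index child's, so same-year siblings (twins) and the
  index child itself count.
* Mothers with `cd > ceb` or missing CEB are dropped with a logged count.

## Problem sizes and what the checks show

The package's acceptance checks train on about 20,000 mothers' complete
histories (4 countries, earlier survey of 2 per country, 5,000 mothers
per survey), hold out the most recent survey of each country, and
estimate from its SBH view — roughly 350,000 person-period rows and
120,000 children, a scale three orders of magnitude below the multi-survey
databases the method is designed for, chosen so the full cycle runs in
minutes on one CPU. At this scale, combined under-five mortality trends
are recovered well (median relative error within a few percent of one,
$R^2 \gtrsim 0.9$ against truth over the 15 pre-survey years), and
expected entrants track observed entrants with log-scale $R^2$ above
0.95. Recovery of *individual* bins is noticeably harder: with only a few
hundred deaths per bin in training, the realized training data
themselves sit several percent away from the generating hazards (frailty
clusters deaths within mothers, and each country's training data carry
one realized survey effect), the model faithfully reproduces those
deviations, and per-bin relative errors of 10–20% in one or two bins are
typical at this size. Interval coverage of true under-five mortality by
the 95% bands is assessed by the test suite for pooled-population trends
at reduced sizes against an 80% bar; single-country bands carry parameter
uncertainty only — realized survey- and country-level effects and the
smoothing of year-to-year structure are treated as signal — so their
coverage is necessarily weaker. These are properties of the method at
small scale, documented here rather than hidden, and they shrink as
training data grow.

## Known limitations

Besides the generator's idealizations listed above: the method cannot
react to mortality shocks shorter than its smooths can represent;
estimates for years after the last training survey rest on extrapolated
trend smooths and are increasingly uncertain; CEB-at-birth for
hypothetical children is an expectation rather than an integer draw;
and the POB distributions are assumed stationary over the tabulation
window (a survey-period stratified tabulation is provided for checking
this assumption, not for lookup).
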
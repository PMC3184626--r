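---
title: "Estimating the productivity costs of CFS/ME: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the productivity costs of CFS/ME: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfsmecosts)
```

## The problem

Adults with chronic fatigue syndrome / myalgic encephalopathy (CFS/ME) are
typically ill for years before they reach a specialist NHS service, and about
half report having discontinued employment because of fatigue-related
symptoms by the time they are assessed. This package implements a
human-capital cost-of-illness analysis for such a cohort: it values the work
lost between discontinuation and assessment at gross average earnings, sums
those losses over sex-and-age strata, and extrapolates them to an annual
nationwide figure via service access rates. Alongside the cost model it
provides the epidemiological toolkit the analysis needs — questionnaire
scoring, descriptive group comparisons, and logistic regression for the
factors associated with discontinuation — plus a synthetic-cohort generator
so that every stage can be exercised and validated without patient data.

## The cost model

For stratum $(a, s)$ (age band $a$, sex $s$) the pre-assessment productivity
loss is the product

$$
L_{as} = N_{as} \; d_{as} \; \frac{m_{as}}{12} \; f_s \; y_{as},
$$

where $N_{as}$ is the number of patients assessed, $d_{as}$ the proportion
who had discontinued employment, $m_{as}$ the median duration of illness in
months, $y_{as}$ the stratum's mean annual income, and $f_s$ the
*unemployment fraction* — the mean, per sex, of the per-patient ratio
(duration of unemployment)/(duration of illness), estimated from an external
sample of patients whose date of discontinuation is known. The fraction is
stratified by sex only: age strata in the external sample are too small to
support an age-specific estimate.

Per-person losses $l_g = \sum_{as \in g} L_{as} / \sum_{as \in g} N_{as}$ are
reported on pooled groups $g$: the 18–21 band is pooled into 22–29 (both
sexes), because the youngest band is too sparse to carry its own population
denominators; all other bands stand alone.

Nationwide extrapolation uses the annual access rate
$r_g = (N_g / T) / P^{\mathrm{PCT}}_g \times 10^5$ — patients per 100,000
catchment population per year, with $T = 4$ study years — multiplied by the
UK population $P^{\mathrm{UK}}_g$ of the group to give projected annual
patients $U_g$, and $U_g \, l_g$ to give the projected annual cost. Totals
are sums of unrounded group values; all arithmetic is at full floating
precision, with rounding applied only at display. This matters: several
right-half cells of the published-style table are only reproducible when the
unrounded per-person losses and rates are carried forward.

Two one-way sensitivity analyses re-run the entire pipeline with one
parameter set to the bounds of its 95% confidence interval, all else fixed:
(i) the unemployment fractions $f_s$, both sexes moved jointly to their CI
bounds; (ii) the discontinued proportions $d_{as}$, all strata moved jointly
to Wilson 95% bounds computed from the stratum counts. The Wilson choice is
ours — no method is canonical here — so the proportion-based interval is
method-dependent and is labelled as such; the base case always lies inside
both intervals.

## Questionnaire scoring

Four inventories are scored from item responses: the 11-item Chalder Fatigue
Scale (0–3 per item, total 0–33), the 10-item SF-36 physical function
subscale (items 0/5/10, total 0–100, higher = less disabled), and the two
7-item HADS subscales (0–21 each); a 0–100 visual-analogue pain rating
passes through unscored. The missing-item rule is: more than one unanswered
item codes the total (or HADS subscale) as missing; exactly one unanswered
item yields an adjusted total. The adjustment formula is not fully
standardised in the field, so we pro-rate by $n/(n-1)$ — equivalent to
imputing the mean of the answered items — and round half-up to the
instrument's attainable grid (multiples of 5 for the SF-36 subscale). This
is the only scale-preserving linear choice, and it keeps every total inside
its printed range; an exhaustive enumeration over small item vectors in the
test suite confirms bounds, monotonicity and the mean-imputation
equivalence.

For regression, each score is rescaled to the common range 0–10 by
`score * 10 / scale_max` (exactly, not approximately), so that odds ratios
per unit are comparable across instruments.

## Regression models

Discontinuation (temporary + indefinite pooled) versus current employment is
the binary outcome; records with status "other" or missing are excluded from
it, but "other" is retained as its own category elsewhere — it is not
merged with missing, since the two arise differently on the source forms.
Covariates are: age as a linear per-decade term (band midpoint / 10, so a
single odds ratio per decade), sex, illness duration in years, and the five
rescaled symptom measures; every model additionally adjusts for centre and
assessment year as unordered categorical indicators (reference = first level
alphabetically; no coding is canonical). *Partially adjusted* models fit one
covariate at a time plus centre and year; the *fully adjusted* model fits
all covariates jointly. All models are fitted on the complete-case set for
the full covariate list, so the partial and full fits share one analysis
population and report the same n.

The fitter is iteratively reweighted least squares written for this package:
Newton updates with step halving (the log-likelihood trace is non-decreasing
by construction), convergence when the largest absolute coefficient change
falls below 1e-8, capped at 100 iterations. Wald 95% intervals are
exponentiated to the odds-ratio scale. Complete or quasi-complete separation
is flagged as non-convergence with a diagnostic rather than reported
silently, and a rank-deficient design is an error naming the collinear
columns. The test suite holds the fitter to the closed-form cross-product
ratio on 2×2 designs (to 1e-6) and to `stats::glm` on full models; `glm` is
used only as a cross-check, never as the implementation.

Group comparisons report medians and interquartile ranges (linear
interpolation between order statistics — no quantile rule is canonical) with
available-case counts per variable. Association tests are Pearson
chi-squared without continuity correction for categorical variables, the
pooled-variance two-sample t-test for continuous ones (a rank-based
alternative can be reached through `stats::wilcox.test` on the same frame
but is not the default), and a Cochran–Armitage trend test
(`stats::prop.trend.test`) across ordered levels.

## The unemployment-fraction estimator

Two definitions circulate for $f_s$: the mean of per-record ratios, and the
ratio of mean durations. They differ in general; we implement both and
default to the mean of ratios, which treats each patient's trajectory as one
observation and supports the plain t-interval
$\bar r \pm t_{n-1,0.975}\, \mathrm{SE}(\bar r)$ used here. The
ratio-of-means variant carries a delta-method interval. Records with zero
illness duration are rejected with a diagnostic; unemployment exceeding
illness duration is *not* rejected (dates on forms can legitimately produce
it), only propagated.

## The synthetic generator

`simulate_cohort()` emulates the assessed cohort the analysis was designed
for, with every default chosen once, up front, from the cohort's published
marginal structure: 2,170 patients of whom 76.9% are women; mean ages 41.4
(men) and 38.6 (women) with SD 11.5 years, truncated to the eligible 18–64
range; log-normal illness durations (medians and IQRs of such durations are
strongly right-skewed, and the log-normal is the simplest positive family
matching a median and spread) with meanlog log(42) and sdlog 1.05;
employment status generated from a logistic model on the banded age-decade
term, sex, duration in years and the rescaled true scores, with intercept
0.60 so that about 55% of resolvable statuses are discontinued; status
recorded for 91.8% of patients, 9.1% of recorded statuses "other", and
temporary vs indefinite split 322:676. Under these defaults the employed and
discontinued groups have median illness durations of about 35 and 48 months
respectively — the generator's calibration anchors.

Inventory items are generated by thresholding a latent per-patient severity
(loading 0.6) through correlated uniforms mapped onto each item's ordinal
grid, so totals have realistic medians and are positively correlated within
patient; the exact item-level correlation structure of the real instruments
is *not* modelled. Missingness is missing-completely-at-random by default:
one whole-booklet draw per patient (93% returned) shared by all instruments,
plus small per-instrument one-item (still scored, pro-rated) and two-item
(total missing) rates, and 9% missing durations — jointly giving roughly the
complete-case fraction the analysis models see (~79%). A configuration
switch (`status_missing_model = "age_fatigue"`) makes status missingness
increase with age and fatigue, for probing the sensitivity of complete-case
analyses. Covariates are independent given sex except through the latent
severity; no joint age-duration structure is imposed.

Randomness uses a single stream seeded once per run, with a fixed vectorised
draw order, so identical (config, seed) pairs reproduce identical records on
any platform. `true_parameters()` exposes the exact coefficients a run used,
which is what the parameter-recovery and coverage tests consume.

What passing tests on this generator do and do not show: they demonstrate
that the estimators are correct *under the generative model* — unbiased
coefficient recovery, nominal Wald coverage, correct complete-case behaviour
under MCAR. They cannot validate the published odds ratios or medians
themselves (the patient-level data are not public), and real missingness is
not MCAR, real items are more strongly structured, and real covariates are
correlated. The published regression results serve only as calibration
anchors, never as reproduction targets.

## Problem sizes and numerical choices

The packaged reference inputs (stratum summaries, incomes, populations,
fractions) drive the whole cost pipeline in well under a second. The
simulation-based guarantees in the test suite use sizes chosen to make the
statistical assertions sharp while keeping the suite quick to iterate on:
parameter recovery at n = 20,000 (each coefficient within 3 SE of truth),
Wald coverage over 200 cohorts of n = 5,000 (coverage within [92%, 98%] per
coefficient), and fraction-estimator unbiasedness over 1,000 external
samples of n = 60. Ties in the pro-rating grid round half-up; medians use
type-7 quantiles; IRLS starts from the zero vector; currency is never
rounded internally.

## Known limitations

Incomes are applied retrospectively at a single price year with no
discounting, matching the human-capital convention adopted here; a
friction-cost valuation would give smaller figures and is out of scope. The
extrapolation assumes the five contributing services' access rates transfer
to the UK as a whole. The proportion-based sensitivity interval depends on
the Wilson choice. No multiple imputation, interaction terms or model
selection is offered, and the six-month cost comparator sometimes quoted for
primary-care chronic fatigue populations is deliberately not computed — its
weighting is under-specified.
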
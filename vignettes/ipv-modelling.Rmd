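---
title: "Modelling national, regional, and global IPV prevalence"
author: "ipvmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling national, regional, and global IPV prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Population surveys of intimate partner violence (IPV) are hard to compare.
They differ in the recall window (lifetime vs the past 12 months), in the
definition of violence (physical and/or sexual, physical only, sexual
only, severe acts only), in who was asked (ever-partnered women, all
women, currently partnered women), in which perpetrators count (any
current or previous partner vs the current/most recent one), in
geographic representativeness (national, urban-only, rural-only), and in
how ages are reported (5-year bands vs a single broad 15--49 figure).
Many countries have one or two surveys at most; some have none. Producing
country, regional, and global prevalence series from this material
requires a model that harmonizes instruments, shares information across
the geographic hierarchy, and propagates every recognized source of
uncertainty into the reported intervals.

`ipvmeta` implements such a framework end to end: survey pre-processing,
crosswalk adjustment factors estimated by exact matching within surveys,
a five-level Bayesian binomial meta-regression with spline age and time
effects fitted by Gibbs sampling (JAGS), age-standardization of wide age
bands, joint constraints linking the two recall windows,
uncertainty propagation over sampled adjustment vectors, population-
weighted aggregation, and validation by posterior predictive checks and
held-out cross-validation. A synthetic database generator with known
ground truth makes the whole pipeline testable offline.

## The model

For observation $i$ at calendar year $t$, the survey-adjusted count of
women reporting violence is binomial,
$y_{it} \sim \mathrm{Binomial}(p_{it},\, N_{it})$, with
$$\mathrm{logit}(p_{it}) = \alpha_{s[i]} + \gamma_{c[i]} + \delta_{c[i],t} + X_{s[i]}.$$

* **Intercepts.** $\alpha_{s[i]} = u_g + u_z + u_r + u_c + u_s$: world,
  super-region, region, country, and study effects, each normal on the
  logit scale. The global intercept has a diffuse N(0, variance 1000)
  prior; the super-region, region, and country scales have half-Cauchy(0,
  25) priors. Study effects have scale $\sigma_n$ for nationally
  representative studies and $\sigma_n + \tau$ for sub-national ones, so
  sub-national surveys are never weighted more than national ones.
* **Age.** Each country has its own age pattern
  $\gamma_c(a) = \sum_k \lambda_{c,k} A_{a,k}$ built from a natural cubic
  spline basis with hierarchical coefficients
  $\lambda_{c,k} = \eta_{g,k} + \eta_{z,k} + \eta_{r,k} + \eta_{c,k}$.
  Candidate interior knots are one of 20/25/30/35 or the pairs (20,35),
  (20,40), (25,35), (25,40), compared by WAIC (DIC reported alongside).
  The basis is evaluated at 5-year band midpoints, centered at age 30,
  and ages above 65 are recoded to 65 so prevalence is constant in the
  open-ended 65+ band (data are too sparse there to estimate a shape).
* **Time.** A natural cubic spline in calendar year with one interior
  knot at 2011 (the median year of data collection), centered at the
  knot, again with global/super-region/region/country coefficient levels.
* **Crosswalk offsets.** $X_{s[i]} = \sum_j \beta_j C_{s[i],j}$, the sum
  of log odds ratios for whichever non-reference instrument features the
  observation has. An all-zero indicator vector means the observation is
  already on the gold-standard scale.
* **Age-standardization.** For a band wider than five years, $p_{it}$ is
  the population-weighted mean of the age-cell prevalences over the
  band, using the observation's region's 2010 female age distribution.
  This is what lets broad 15--49 figures and 5-year bands inform the same
  age curve coherently.

## Pre-processing

Missing age-specific denominators are allocated from the study total
proportionally to the country's 2010 female age distribution; studies
with no sample size at all get 3,000 (national) or 1,000 (sub-national)
respondents. Effective sample sizes account for complex survey design:
a reported design-adjusted 95% CI is inverted through the Wilson score
formula (applied to the upper limit; bisection to 1e-6), a reported SE
gives $p(1-p)/SE^2$, and otherwise the denominator is divided by a
design effect of 2.5 (the median from standardized DHS analyses, taken
here as a given constant). Missing end years fall back to the
publication year; missing upper ages become open-ended bands. The
binomial count is formed as $y = \mathrm{round}(p \cdot N_{eff})$,
the minimal-distortion choice.

Two datasets are then built. The *adjustment dataset* keeps the broadest
age band per study, outcome, and instrument combination and feeds the
crosswalk. The *modelling dataset* applies the four ordered optimal-set
rules (all severities over severe-only; physical and/or sexual over
physical-only over sexual-only; ever-partnered over all-women over
currently-partnered; any partner over current/most-recent), keeps the
most granular non-overlapping age strata so no woman is double-counted,
and drops urban/rural strata when the same study reports a national
estimate.

## Crosswalk factors

Including instrument indicators directly in the meta-regression risks
compositional bias (surveys needing an adjustment may cluster in high-
or low-prevalence settings), so adjustment factors are estimated outside
the model by exact matching: within each survey, an observation at a
non-reference level is paired with one at the reference level that is
identical on every other matching dimension, including the age band.
When several candidate pairs exist, the one closest to the optimal set
wins (most reference-level fields, ties broken in the rule order). Each
pair yields an odds ratio with the standard 2x2 SE; pairs are pooled by
DerSimonian--Laird random-effects meta-analysis (REML available via the
`method` argument), stratified by super-region, and a super-region
stratum is used only when it contributes more than three pairs --
otherwise the overall factor stands in. Geographic strata (urban/rural
vs national) are not binary, so they use a random-effects logistic
regression on grouped counts restricted to surveys reporting all three
strata, with a random intercept per survey and urban/rural slopes varying
by super-region. The all-women factor for past-year IPV reuses the
lifetime factor, since past-year matching yields essentially no pairs.

Factor uncertainty is propagated by Latin hypercube sampling of complete
adjustment vectors from Normal(log OR, SE) distributions -- truncated
above at zero for factors structurally bound at the null (severe-only,
physical-only, sexual-only, all-women, which measure subsets and cannot
raise the odds; truncation is applied to the sampling distribution, not
post-hoc clipping, so each vector comes from a proper distribution).
The model is refitted once per vector and the posteriors are mixed with
equal weight, so reported intervals carry both within-fit and
between-vector variability (`fit_mixed_over_adjustments()`).

## Constraints linking the two outcomes

Past-year prevalence cannot exceed lifetime prevalence, and among 15--19
year olds the two recall windows largely coincide, so the lifetime to
past-year ratio is capped at 3. The package fits the two outcomes as
aligned single-outcome models and enforces the constraints by joint
rejection of prediction draw pairs (`apply_constraints()`,
`constrained_predictions()`); draws violating either rule at any target
cell are discarded, and an acceptance rate below 1% raises an error
suggesting misfit. The constraints bind at prediction for countries
lacking data on one outcome -- exactly where the joint information has
value; elsewhere the data already keep the two outcomes ordered. A
deterministic projection mode (`mode = "cap"`) is available when a
rejection-free variant is preferred; a likelihood-level soft penalty was
considered and declined, since it would require a genuinely joint
sampler while the rejection approach reproduces the
fitted-with-and-without-constraints comparison directly.

## Computation

Sampling uses JAGS (Gibbs). The full-scale profile
(`mcmc_config("full")`) runs 4 chains of 50,000 iterations with 10,000
adaptation and 5,000 warm-up, thinned every 20th draw (2,250 retained
per chain). The default desk profile -- 2 chains of 4,000 iterations,
500 adaptation, 1,000 warm-up, thinning 2 -- is sized for the synthetic
fixtures used throughout the tests and vignettes: the 40-country desk
fixture fits in well under a minute per outcome. Convergence is
assessed by the potential scale reduction factor (pass threshold 1.05
near one) and a minimum of roughly 1,000 effective samples for reported
quantities; `traceplots()` exports traces. Because any sampler's draws
depend on its engine and version, small numeric differences from other
Gibbs implementations are expected; all seeded runs are reproducible
under a fixed backend.

## Post-processing

Country predictions invert the prediction equation per posterior draw
(without study effects or crosswalk offsets -- predictions are on the
gold-standard instrument scale). Countries without data inherit their
region's curve plus fresh country-level deviations sampled per draw
from N(0, $\sigma_c$) and the corresponding spline-deviation scales,
which properly widens their intervals; by default imputed countries
share the regional time trend exactly (only the paper trail for the
intercept is unambiguous) and `time_deviation = TRUE` enables fresh
trend deviations. Broad age groups and higher geographic levels are
aggregated by summing affected women: age weights are the 2018 female
population times the proportion of women who ever had sex (a better
proxy for ever-partnered exposure than marriage), and regional/global
figures divide summed numerators by summed weights per draw. Summaries
are posterior medians with equal-tailed 95% credible intervals
(medians for robustness; configurable).

## Validation

`posterior_predictive_check()` compares each observation (with its
Wilson interval) against the fitted probability on the observation's own
instrument scale -- study effect and crosswalk offset included -- plus a
replicated-count predictive interval; `plot()` renders the regional
panels. `in_sample_metrics()` reports the median error (observed minus
predicted, percentage points), median absolute error, and the shares of
observations outside the 95% CrI. Coverage is computed against the CrI
of $p_{it}$ by default, with the replicated-data predictive interval
available in the check table. `out_of_sample_cv()` re-fits with 20% of
countries (stratified by region so no region empties) or 20% of studies
held out, 20 repeats by default, and reports across-repeat medians;
held-out countries are predicted by regional imputation and held-out
rows are compared on their instrument-adjusted scale, which is required
for a like-with-like comparison of non-reference surveys.

## The synthetic generator and what passing tests mean

`make_fixture()` draws a world from the model's own generative
distributions: nested intercepts, spline age/time patterns, study
effects with the national/sub-national variance split, then surveys
with mixed instruments, mixed age reporting (broad 15--49 rows plus
5-year bands), national/urban/rural strata, missing denominators, and
design-deflated binomial counts. Defaults are the study conditions the
framework targets: logit-scale intercepts putting lifetime prevalence
near 27% and past-year near 13% at age 30 in 2011; a lifetime age curve
rising from ~0.22 at 15--19 to a plateau of ~0.32 and a past-year curve
declining from ~0.14 to ~0.05 (their 15--19 ratio of 1.6 respects the
joint constraints with margin); true adjustment odds ratios echoing the
reported crosswalk magnitudes (e.g. physical-only 0.86, sexual-only
0.26, currently-partnered 0.91 for lifetime); 85% nationally
representative studies; and per-covariate adjustment shares matching
the global study database, with a 30% gold-standard-instrument study
share reproducing the observed excess of fully reference observations
over what independent covariates would give (about 45% of rows need no
adjustment). Population tables use a smooth declining age pyramid and
an ever-had-sex proportion rising from 0.42 at 15--19 to 1 by the
thirties; both are synthetic stand-ins, not real demography.

Three profiles are used throughout: `tiny` (2 super-regions, 3 regions,
6 countries) for unit tests, `desk` (7 super-regions, 21 regions, 40
countries, roughly 60 studies) for integration and recovery checks, and
`paperlike` (160 countries, ~300 studies, ~3,000 age-specific rows
across both outcomes) for crosswalk recovery at realistic scale. The
desk-scale recovery check uses the default desk MCMC profile and
evaluates 440 country-age cells; its credible intervals sit at or
slightly above nominal coverage because cells within a country share
draws and most synthetic countries have one or two studies, so the
expected-coverage band used in the checks is 88--100% around the 95%
target, and the median recovery error is required to stay under one
percentage point.

Passing these tests shows the pipeline is internally coherent -- the
generator and likelihood are one model family, estimators recover known
truth, uncertainty propagates -- but not that real survey data satisfy
the model's assumptions (no reporting bias, exchangeable study effects,
smooth age/time patterns). Conclusions about real data still require
the posterior predictive checks and held-out validation run on that
data.

## Numerical choices and edge cases

* Wilson inversion brackets $n$ in [1, max(10 n, 1e4)] and falls back to
  the design-effect rule with a warning when the reported interval is
  inconsistent with any sample size; no continuity correction is used.
* Zero cells in a matched 2x2 table get the standard 0.5 correction on
  all four cells (logged via a message).
* "Broadest age band" is maximal width with ties broken toward the band
  covering the most 5-year cells; exact duplicates that survive
  optimal-set selection raise an error naming the observations.
* Mixed urban/rural sub-national surveys carry no geographic adjustment
  indicator but keep the sub-national variance class.
* The N(0, 1000) priors are read as variance 1000 (precision 0.001),
  the convention of precision-parameterized Gibbs samplers.
* Observations needing a covariate whose factor could not be estimated
  stop the model build; `filter_adjustable()` removes them explicitly
  when that is the intended analysis decision.
* The convergence screen used when many sub-fits run unattended
  (mixture fits, cross-validation repeats) checks the PSRF of the
  reported prevalence nodes with a lenient 1.5 threshold; weakly
  identified variance hyperparameters on small fixtures can show large
  PSRFs without disturbing the reported quantities.

## Known limitations

Psychological IPV and non-partner sexual violence are out of scope, as
are country-level predictive covariates (previous work found no
consistent relationships, and adding them would not help the many
countries that do have data). The recall-period adjustment for "past
two years or more" is not estimated -- no studies require it. Estimates
for countries without data are exchangeable draws within their region;
they borrow no country-specific information. Self-report measurement
bias is not modelled: if disclosure differs systematically across
settings, harmonized estimates inherit that bias.
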
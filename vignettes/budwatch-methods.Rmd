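---
title: "Modelling wetland birdwatching visitation and its value: methods"
author: "budwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wetland birdwatching visitation and its value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budwatch)
```

## Overview

`budwatch` implements a chain from citizen-science bird checklists to an
economic statement about wetland condition: monthly visitation counts are
derived from checklist postings, regressed on weather and wet-surface-area
covariates, the fitted coefficients are translated into projected
visitation changes under a wet-area increase, and those changes are priced
with survey-based expenditure rates. This vignette documents the model,
the synthetic-data generator that stands in for restricted microdata, and
every numerical and design choice a user might want to interrogate.

## From checklists to monthly series

A checklist record is one species entry on a posted list (columns
`checklist_id`, `birder_id`, `hotspot_id`, `date`, `species`). The
visitation proxy is the **Birder User Day** (BuD): one distinct
(birder, date) pair at a hotspot, regardless of how many lists that birder
posted that day. Monthly **species richness** is the count of unique
species across all lists posted from the hotspot that month, reported for
all species and for a freshwater/freshwater-edge "long list" subset;
matching against the long list is exact after trimming and case-folding
(the list is fixed, so fuzzy matching would only add false positives).
Months with no postings are materialized as explicit zero rows: the
regressions need a complete `1..T` panel. A checklist is assigned to its
recorded start date, and each posting birder counts separately — the data
model carries no information about shared group lists.

## Covariates

* **Rainfall**: for hotspots spanning several weather grid cells, daily
  rainfall is averaged across cells, then summed over the month (mm).
* **Temperature**: daily maximum temperature is averaged across cells and
  then across the month (deg C).
* **Wet surface area**: each month's combined waterbody wet area is
  expressed as a percentage of the site's maximum observed wet area over
  the window. Cloud cover can hide the surface: months with less than 50%
  of the maximum area visible (threshold configurable) are flagged and
  gap-filled by linear interpolation between the nearest valid neighbours.
  Two choices here were genuinely open. First, the maximum in the
  denominator is taken over *valid* months only — an obscured month can
  only undercount, so letting it set the maximum could never raise and
  might spuriously lower every other month's percentage. Second, flagged
  months at the window's edges have only one valid neighbour; they are
  filled by nearest-valid-value extension with a logged warning, the
  minimal-assumption completion of a rule defined for interior breaks.
  Interpolation is idempotent and interior fills are bounded by their
  bracketing values; both properties are tested.

## The count models

Monthly BuD and richness counts are non-negative integers, so both are
modelled with count regressions under a log link:

$$\ln \mu_t = \beta_1 + \beta_2\,\mathrm{Rain}_t + \beta_3\,\mathrm{MTemp}_t
  + \beta_4\,\mathrm{Wet}_t \;\text{or}\; \beta_5\,\mathrm{Wet}_{t-1}
  + \beta_6\,\mathrm{Spp}_{t-1} + \beta_7 f(\mathrm{month}_t) + \beta_8 t$$

Month-of-year enters as an 11-indicator factor whose reference level is the
month-of-year of month index 1 (April for the default window — an arbitrary
but fixed and documented choice), and the month index supplies a linear
trend. At least 14 months are required to identify the month effects plus
trend. Five candidate driver sets are fitted for BuD (current wet; lagged
wet; lagged richness; current wet + lagged richness; lagged wet + lagged
richness) and two for richness (current or lagged wet). Current and lagged
wet percentage never co-occur: a variance-inflation-factor screen excludes
any candidate whose continuous columns include a VIF above 3, and the
wet/lagged-wet pair is the canonical failure (perfect collinearity reports
an infinite VIF rather than crashing).

**Estimation.** The Poisson model is fitted by iteratively reweighted least
squares, converging when the relative log-likelihood change drops below
1e-10 (at most 100 iterations); non-convergence is an error carrying the
likelihood trace. The NB2 negative binomial (variance
$\mu + \alpha\mu^2$) is maximized jointly over $(\beta, \alpha)$ by
alternating Fisher-scoring steps for $\beta$ with a one-dimensional search
over $\log\alpha$; $\alpha \ge 0$ is enforced by the log parameterisation,
and when the search lands at the boundary the fit collapses exactly onto
the Poisson solution, which keeps the likelihood-ratio statistic
non-negative by construction. A near-singular information matrix — e.g.
separation from a month-of-year level whose counts are all zero — receives
a ridge jitter of 1e-8 on the information matrix with a warning; genuine
rank deficiency of the design is an error. The IRLS solution satisfies the
score equations $X^\top(y-\hat\mu)=0$ to 1e-8 and, with an intercept, the
fitted means sum to the observed counts; both are tested, along with
cross-checks against `stats::glm` and `MASS::glm.nb` as independent
optimizers.

**Functional form and model choice.** Within each candidate, Poisson versus
NB2 is decided by the likelihood-ratio test on $\alpha$. Because
$\alpha = 0$ sits on the boundary of the parameter space, the statistic
$2(\ell_{NB} - \ell_P)$ is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; NB2 is preferred at p < 0.05.
Across candidates the best model is the AIC minimiser: the candidate sets
are not nested, which rules out sequential testing, and AIC is the
standard tool for that comparison. A deviance-based pseudo-R-squared
(`1 - deviance/null deviance`) is reported for every fit — one of several
defensible definitions, so it is stated here explicitly — together with
its "linear equivalent", the squared correlation between fitted and
observed counts.

**Inference.** Standard errors are Newey–West HAC: a sandwich whose meat
applies Bartlett weights $w_\ell = 1 - \ell/(L+1)$ to the score
autocovariances and whose bread is the inverse expected information. The
default truncation lag is the plug-in $\lfloor 4 (T/100)^{2/9} \rfloor$
(3 at T = 72), configurable. The meat carries an $n/(n-k)$
degrees-of-freedom correction: with 16 design columns on a 72-month
series, uncorrected sandwich standard errors are noticeably biased
downward, and the correction (the same one classical HAC software applies)
restores near-nominal coverage — across 500 synthetic 72-month panels the
HAC 95% intervals cover the generating wet coefficient about 92% of the
time. At lag 0 the estimator reduces exactly to the White
heteroskedasticity-robust sandwich.

## The panel model

Pooling the hotspots, a fixed-effects Poisson model absorbs site-specific
intercepts through the conditional (multinomial) likelihood: conditioning
each site's counts on their total leaves cell probabilities
$p_{it} = e^{x_{it}\beta}/\sum_s e^{x_{is}\beta}$, free of the fixed
effects, and the conditional MLE coincides with the dummy-variable Poisson
slopes (tested to 1e-6). Month-of-year and trend are shared across sites.
Newton iterations with step-halving converge on the same 1e-10 relative
tolerance. All-zero sites carry no conditional information and are dropped
with a warning.

Panel inference is a hotspot-clustered bootstrap: entire site series are
resampled with replacement (999 replicates by default — the replication
count is not pinned down externally, so it is configurable), each refit
produces a coefficient vector, and their covariance is the bootstrap
covariance. Duplicate resampled sites get distinct cluster labels so each
refit is well-posed; a replicate with fewer than two distinct sites is
redrawn (at most ten times). With only ten clusters, normal critical
values undercover; `confint()` therefore uses t quantiles on $G-1$ degrees
of freedom, the standard few-cluster practice, which brings coverage of
the generating wet coefficient to roughly 94% across simulated panels.

## Scenario projection

A wet-area increase is specified by `wet_scenario(percent, mode)`. The
published phrase "a 15% increase in wet surface area" does not pin down a
baseline, so both readings are supported and the choice is recorded in the
result: the default **relative** mode takes $\Delta x$ = 15% of the site's
mean wet percentage (a proportional improvement on typical condition); the
**absolute** mode applies 15 percentage points directly.

* **Direct chain**: percent BuD change $= 100(e^{\beta_{wet}\Delta x}-1)$
  from a fit containing the (typically lagged) wet term.
* **Mediated chain**: the expected richness change
  $\Delta S = S_{base}(e^{\beta^{rich}_{wet}\Delta x}-1)$ at baseline
  richness $S_{base}$ (default: the site's mean observed richness) is fed
  through the lagged-richness coefficient of the BuD model:
  $100(e^{\beta^{bud}_{spp}\Delta S}-1)$.

Percentile bands (5th/50th/95th) come from 10,000 seeded draws of the
coefficients from normal distributions with their HAC standard errors —
the estimator's asymptotic distribution is the minimal assumption when no
band-construction method is given externally; the two links of the
mediated chain are drawn independently. A fit whose wet (or richness) term
is not significant at p < 0.05 yields a result flagged `ns` — the
threshold choice between 0.05 and 0.10 was open and 0.05, the stricter
convention, is the default. As the coefficient uncertainty vanishes the
band collapses onto the point estimate.

## Expenditure valuation

Survey respondents report eBird usage, usual travelling-group size (alone,
pair, group of 2–5, group > 5), categorical day- and overnight-trip
frequencies, and per-day costs. The arithmetic is deliberately plain:

* **Frequency mapping**: closed categories map to trips/year through a
  configurable table; the top category ("more than two trips a week") maps
  to 144 (three trips a week over 48 weeks, excluding holiday periods),
  and intermediate categories use midpoints.
* **Activity weights**: per cohort (eBirders / non-eBirders), the share of
  activity in each (group, trip-type) cell is the group-membership
  proportion times that group's day-versus-overnight trip share,
  normalized to sum to one. Respondents in groups larger than five are
  excluded from expenditure cells — one person's reported spend is a poor
  proxy for a large group's — but retained in eBird-usage proportions.
* **Cell statistics are medians**, not means: trip-frequency distributions
  are heavily right-skewed, and medians keep the estimates conservative.
  Ties take the lower middle order statistic (the value at position
  $\lceil n/2 \rceil$), a documented convention where none is prescribed.
* **Per-visit-day and annual expenditures** are the weight-by-median sums;
  being convex combinations they are bounded by the cell extremes.
* **Extrapolation**: the non-eBirder to eBirder usage ratio converts BuDs
  into expected non-eBirder visit days (0.383 in the published tables).
* **Site totals**: annual BuDs (from the last complete calendar year)
  times the eBirder rate, plus extrapolated non-eBirder days times the
  non-eBirder rate. Scenario deltas scale this total by the projected
  percent BuD change; an `ns` scenario returns an explicit not-applicable
  sentinel rather than a number. Currency is nominal AUD throughout.

The published activity proportions and medians ship as
`mdb_reference_tables()`: the microdata behind them are restricted, so
when reproducing the published worked example they are inputs, not
outputs.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `sim_study()` draws all four
inputs from them. Defaults emulate a ten-hotspot, 72-month window from
April 2013 (2,191 days), around ten BuDs per hotspot-month from a pool of
1,060 birders, and a 76-respondent survey of which 59 are usable.

* **Weather**: per grid cell, daily rainfall is gamma around a weak
  seasonal sinusoid (variance 0 degenerates to the mean exactly) and
  maximum temperature a southern-hemisphere sinusoid plus noise. Rainfall
  seasonality is kept weak (amplitude 0.15) so that monthly rainfall and
  temperature are only moderately correlated — the emulated study entered
  both in every model, which requires their collinearity to clear the VIF
  screen; inland-basin rainfall is in any case weakly seasonal.
* **Wet area**: a seasonal AR(1) fraction of the site maximum; a
  configurable fraction of months (default 0.2) is cloud-obscured
  (visible fraction below 0.5) and undercounts area proportionally, while
  adequately visible months are treated as fully observed, so with clear
  skies the analysis recovers the ground-truth percentages exactly.
* **Richness**: each species occurs each month with probability logistic
  in wet percentage (water-flagged species respond twice as strongly),
  plus a common month-level logit shock (sd 0.4) representing reporting
  effort and detection noise. The shock matters: without it richness is a
  near-deterministic function of wet area, which neither resembles
  checklist-derived richness (the emulated study's richness models fit
  far worse than its visitation models for exactly this reason) nor
  allows wet and richness terms to coexist in one regression.
* **BuDs and checklists**: monthly BuD counts are Poisson with log-mean
  given by the generating coefficients applied to the derived monthly
  covariates; defaults are paper-scale (wet effect 0.02 per percentage
  point, small negative rain and temperature effects, mild seasonality
  and trend). Each BuD is realized as a distinct (birder, day) pair —
  visit days fall uniformly over the month, the simplest assumption where
  within-month timing is undescribed — and posts a shifted-geometric
  number of checklists with mean 1.5, matching the observed ratio of
  about 1.5 postings per visit day. Checklists sample species from the
  month's occurring set, and every occurring species is pinned to at
  least one list, so observed monthly richness equals the generating
  richness whenever the month has any visits.
* **Survey**: respondents fall into basin-eBirder / basin-non-eBirder /
  non-basin cohorts (69.1 / 26.5 / 4.4% by default), draw group and
  frequency categories from configurable tables, and report lognormal
  expenditures around the published cell medians (so cell medians are
  recoverable).

All randomness flows from the single master seed through named per-stage
streams; a fixed seed gives byte-identical output, and no generator
function disturbs the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: spatial structure of hotspots and weather,
species phenology and turnover, birder behaviour (popularity dynamics,
effort covariates such as list duration or distance, group checklists),
platform growth over time, and any travel-cost behavioural response. The
generator demonstrates that the estimators recover known parameters under
the stated sampling assumptions, not that those assumptions hold in any
particular field dataset.

## Problem sizes used in validation

The test suite validates the statistical machinery at these scales, chosen
to make Monte-Carlo error small relative to the bands being checked while
keeping the default test run brisk: 500 synthetic 72-month panels for HAC
interval coverage; 1,000 replicates for the size of the overdispersion LR
test under the Poisson; 200 strong-signal panels for candidate-selection
consistency; 100 ten-site panels (99 bootstrap replicates each) for
cluster-bootstrap coverage; and a full ten-site, 72-month pipeline run for
end-to-end closure.

## Known limitations

* Associations, not causes: the scenario projections condition on "all
  other drivers unchanged" and inherit every identification caveat of the
  underlying regressions.
* HAC corrects residual autocorrelation but the month terms are assumed to
  capture its bulk; no ARMA error structure is modelled.
* Few-cluster bootstrap inference is approximate even with t quantiles.
* The expenditure arithmetic ignores sampling error in survey medians and
  any regional economic multipliers; international visitors are out of
  scope.
* Zero-inflation and smooth (GAM-type) seasonality are deliberately not
  modelled.
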
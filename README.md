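# budwatch

Count-regression modelling of birdwatcher visitation at wetland sites from
citizen-science checklist data, with scenario projection of visitation
change under improved wetland condition and survey-based valuation of the
associated birdwatching expenditure.

## The problem

Wetland managers weighing environmental-water decisions rarely have direct
visitation data. Checklists posted to citizen-science platforms such as
eBird are a cheap, dense proxy: each posting is a geo-located, dated species
list from an identifiable birder. `budwatch` aggregates postings into
monthly **Birder User Days** (BuDs) — distinct (birder, date) pairs at a
site — and monthly **species richness** (unique species reported, in total
and for a freshwater-habitat "long list"), and asks how these respond to
wetland condition, proxied by the **wet surface area** of the site's
waterbodies as a percentage of its observed maximum.

The package is aimed at statistical ecologists and environmental economists
who want the whole chain — data aggregation, count regression, scenario
projection, expenditure valuation — as tested, reusable functions. Because
raw eBird and survey microdata are restricted, a first-class synthetic-data
generator with known ground-truth parameters replaces them, so every stage
is verifiable end to end.

## The model

For each hotspot, monthly counts (BuD or richness) follow a Poisson or NB2
negative-binomial regression with log link:

    BuD_t ~ Poisson(mu_t)          (or NB2: Var = mu_t + alpha * mu_t^2)
    ln mu_t = b1 + b2 Rain_t + b3 MTemp_t
              + b4 WetPxPc_t  or  b5 WetPxPc_{t-1}
              + b6 SppCt_{t-1} + b7 f(Month_t) + b8 t

where `Rain_t` is monthly total rainfall (mm), `MTemp_t` mean daily maximum
temperature (deg C), `WetPxPc` the wet-area percentage (current or lagged —
never both; their collinearity fails a VIF > 3 screen), `SppCt_{t-1}` lagged
richness, `f(Month_t)` an 11-level month-of-year factor and `t` a linear
trend. Five candidate driver sets are fitted for BuD and two for richness;
the functional form is chosen per candidate by a boundary likelihood-ratio
test on `alpha` (reference distribution `0.5*chi2_0 + 0.5*chi2_1`), and the
best candidate by AIC. Inference uses Newey–West HAC standard errors with
Bartlett-kernel weights and an `n/(n-k)` finite-sample correction. A
fixed-effects Poisson panel model (conditional likelihood, site intercepts
eliminated) pools all hotspots, with hotspot-clustered bootstrap standard
errors.

Fitted coefficients translate into scenario projections for a wet-area
increase `dx`: the direct chain gives `100*(exp(b_wet * dx) - 1)` percent
BuD change, and the richness-mediated chain composes the wet-to-richness
and richness-to-BuD links; 5th/50th/95th percentile bands come from
parametric coefficient draws. Expenditure valuation weights median survey
costs by traveller-category activity proportions, extrapolates eBirder
visit days to non-eBirders, and scales site annual expenditure by the
projected visitation change.

## Worked example

The published expenditure worked example, reproduced from its printed
inputs (activity proportions and median costs):

```r
library(budwatch)
tab <- mdb_reference_tables()
per_visit_day_expenditure(tab$weights$ebird,    tab$per_day_medians$ebird)
#> [1] 98.1395        # AUD/day, representative eBirder
per_visit_day_expenditure(tab$weights$nonebird, tab$per_day_medians$nonebird)
#> [1] 99.26          # AUD/day, representative non-eBirder
annual_expenditure(tab$weights$ebird,    tab$annual_medians$ebird)
#> [1] 1554.917       # AUD/year
annual_expenditure(tab$weights$nonebird, tab$annual_medians$nonebird)
#> [1] 1184.17        # AUD/year
extrapolation_factor(26.5, 69.1)
#> [1] 0.3835022      # non-eBirder visit days per BuD
```

A complete synthetic study — simulate ten hotspots over 72 months, build
the panel, fit all candidates, project scenarios, value expenditure:

```r
res <- run_study(sim_config(seed = 11), boot_reps = 99)
print(res)
#> Birdwatching visitation study -- 10 hotspots, 72 months
#>   best BuD candidate per hotspot: h01:5 h02:5 h03:5 h04:2 h05:5 h06:2 h07:5 h08:5 h09:2 h10:5
#>   direct scenario median BuD change: +22.6% +17.0% +23.6% +25.4% +21.0% +21.0% +18.9% +21.8% +29.8% +24.7%
#>   per-visit-day expenditure: eBirder 80.52, non-eBirder 100.15 AUD (factor 0.609)

res$scenarios$h01$direct
#> direct-chain scenario (relative 15% wet-area increase) for hotspot h01
#>   BuD change: median +22.6% [5th +14.8%, 95th +31.0%]

res$expenditure$sites$h01$scenario_delta
#> Scenario expenditure change: median +6110 AUD/yr [5th +3992, 95th +8377]
```

The generating wet-area coefficient here is 0.02 per percentage point; the
candidate runs recover it (e.g. hotspot h01's best fit estimates the lagged
wet effect at 0.0175 with the lagged-richness link absorbing part of the
association), the direct scenario medians are positive at every site, and
the projected expenditure change scales the site's annual total by the
projected BuD change.

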
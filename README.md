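# hygienecost

Societal-perspective costing of **universal basic hand hygiene in household
settings** across least developed countries (LDCs): what it would cost, over
a ten-year scale-up, to reach every household that has no handwashing
facility (HWF) with a promotion campaign, a purpose-built facility, and the
soap and water to use it.

The package is aimed at health economists and WASH (water, sanitation and
hygiene) planners who need country-level resource-requirement estimates
with honest uncertainty, and at anyone who wants to stress the assumptions
behind such estimates.

## The model

For each country *c* and stratum *s* (urban/rural), the unserved household
stock in year *y* is

```
U_cs(y) = population_cs(y) / household_size_cs × share_no_facility_cs
```

Scale-up reaches cumulative fraction *t/h* of the year-*t* stock after year
*t* (equal cohorts over an *h* = 10 year horizon); cohort sizes are the
successive differences. Each cohort incurs, per household: a promotion
campaign (5-year useful life, repeated in full), annual top-up promotion at
25% of the campaign cost (skipped in repeat years), an HWF (5-year life,
replaced), and annual soap and water from the year served; each country
additionally incurs a one-off formative-research investment. Costs are
discounted at 3% (year-1 costs undiscounted) and reported in 2019 US$.

Prices come from heterogeneous study datapoints: each is deflated to 2019
in its local currency, converted to international dollars (I$) at PPP,
pooled per category (mean ± SE, gamma prior), and re-localised to each
country's 2019 US$. Price uncertainty is propagated with a 1000-draw Monte
Carlo (one gamma draw per category per iteration, applied to all countries;
quantities fixed), summarised as 2.5th/97.5th percentile intervals.
One-way deterministic scenarios (price CIs, discount rate, useful lives,
economies of scale, home-made HWF, promotion without one-to-one activities)
produce a tornado ordering.

No real country data ship with the package: a seeded synthetic generator
(`reference_fixture()`) emulates JMP-style coverage tables, DHS-style
household sizes, UN-style projections, World-Bank-style deflators/PPP
factors and right-skewed price datapoints calibrated to published
per-household price medians. See `vignettes/costing-model.Rmd` for the full
methods account.

## Worked example

```r
library(hygienecost)

fixture <- reference_fixture()           # 46 synthetic countries, fixed seed
model   <- run_base_case(fixture)        # standardise -> pool -> cost -> discount
print(model$summary)
```

```
Cost summary (2019 US$, discounted, 10-year horizon)
  Total:                 US$24.0 billion
  Promotion only:        US$9.5 billion
  Facilities & supplies: US$14.5 billion
  Capital share:         35%
  Average annual cost by category (US$ million):
    formative     0.478  (0%)
    promotion       585  (24%)
    hwf             255  (11%)
    topup           366  (15%)
    soap            895  (37%)
    water           301  (13%)
```

The total is the discounted 10-year sum across 92 strata; "promotion only"
is formative research + initial campaign + top-up, "facilities & supplies"
is HWF + soap + water. Soap dominates because it recurs for every served
household every year. Adding uncertainty:

```r
mc <- run_monte_carlo(model, mc_config(n_draws = 1000, seed = 1))
print(mc)
#> Monte Carlo result: 1000 draws (seed 1)
#>   total: US$24.03 billion (2.5%-97.5% interval: 20.03-28.32)
```

The interval reflects price uncertainty only — the pooled promotion price
is by far the widest prior, which is why it also tops the tornado:

```r
run_scenarios(model, load_scenario_catalogue())
```

The numbered scripts under `analysis/` run the whole study on the reference
fixture — data generation, price standardisation, base case, Monte Carlo,
sensitivity — writing tables under `results/`.

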
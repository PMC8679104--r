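---
title: "A costing model for universal household hand hygiene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A costing model for universal household hand hygiene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hygienecost)
```

## The model

`hygienecost` estimates, from a societal perspective, what it would cost to
give every household in a set of least developed countries (LDCs) a *basic*
hand hygiene service — a handwashing facility (HWF) with soap and water
available at home — over a ten-year scale-up (2021–2030). The model is a
quantities-times-prices costing: no intervention effectiveness, uptake or
disease burden enters it; the output is a resource requirement, not a
cost-effectiveness ratio.

**Quantities.** Each country is split into urban and rural strata. A
stratum's household stock in year $y$ is its projected population divided by
its average household size; the *unserved* stock is the fraction with no
HWF. Households with a *limited* service (a facility, but soap and/or water
missing at the time of survey) are split by limiting factor — missing soap
only, water only, or both — centred on the observed 47/10/43 average split.
Coverage shares are held at their baseline values for all years: projecting
secular coverage trends is out of scope, so population growth is the only
time-varying quantity.

**Scale-up.** The intervention reaches the unserved stock in equal cohorts,
one per year: the cumulative served fraction after year $t$ is $t/h$ over an
$h$-year horizon. Because populations grow, "equal cohorts" is ambiguous: we
apply the fraction $t/h$ to the *year-$t$* unserved stock (computed from
year-$t$ projections) and take successive differences as cohort sizes. This
reduces to exactly equal cohorts under constant population, keeps the
final-year cumulative coverage at 100% of the final-year stock, and makes
the increments telescope — properties the test suite checks. Sizing cohorts
on the base-year stock instead would leave growth-added households unserved
at the horizon.

**Cost cycles.** Six categories are costed per household reached (formative
research is per country):

| category | kind | cycle |
|---|---|---|
| formative research | software capital | once per country in year 1, 1-year life |
| promotion campaign | software capital | at service start, repeated in full every 5 years |
| top-up promotion | software capital maintenance (recurrent) | 25% of the initial campaign cost, annually |
| handwashing facility | hardware capital | at service start, replaced every 5 years; no capital maintenance |
| soap | recurrent | annually from service start |
| water | recurrent | annually from service start |

Two timing conventions had to be fixed. First, top-up promotion begins the
year *after* a cohort is served and is skipped in years when the full
campaign is repeated — paying both in a repeat year would double-count the
reinforcement the repeat already provides. Under discounting and growth this
cycle yields a top-up/initial cost ratio of roughly 0.6–0.7, whereas letting
top-up run every year after a single campaign would push the ratio above 1.
Second, capital purchases are booked in full in the year incurred, with
repeat purchases at the end of useful life inside the horizon and no
residual-value credit at the horizon end; this makes per-year capital costs
flat (in undiscounted terms) under constant population, which is the
behaviour the time-profile outputs display. An equivalent-annual-cost
utility (`annuitize()`) is provided for users who prefer annuitised capital
reporting; the base case does not use it.

**Discounting** divides year-$t$ costs by $(1+r)^{t-1}$ — year-1 costs
undiscounted, i.e. start-of-year accrual — at $r = 3\%$ in the base case. A
constant unit stream over 10 years therefore discounts to the annuity-due
value $\sum_{t=1}^{10} 1.03^{-(t-1)} \approx 8.786$, which the tests pin as a
closed form.

## Prices

Raw price datapoints arrive in heterogeneous currencies and years. Each is:

1. expressed in the study country's local currency (datapoints reported in
   US dollars are converted at the *price-year* exchange rate — inflation
   must be applied in the economy where the price arose, and the source's
   US$ figure is just a display currency);
2. inflated to 2019 prices with the country's GDP deflator;
3. converted to 2019 international dollars (I$) at the 2019 PPP factor.

Pooling happens on the I$ scale — mean and standard error of the mean per
category — because a US$ mean would be dominated by where the studies
happened to be run: the same I$ value re-localises to very different US$
amounts across countries with different price levels. Pooled means get
gamma priors moment-matched to (mean, SE), reflecting the right skew of
price data; `gamma_from_moments()` round-trips to $10^{-10}$ by
construction. For a category with a single datapoint the SE cannot be
estimated; we impute it as the datapoint times the median coefficient of
variation across categories with $n \ge 2$ (configurable), and flag the
result. Zero-dispersion inputs are rejected rather than silently producing
a degenerate prior.

The pooled I$ mean is re-localised to each country as
$\text{US\$} = \text{I\$ mean} \times \text{PPP}/\text{FX}$ (2019 factors).
A single national price per category is used — price differences between
urban and rural areas are a known limitation of the underlying data, not
modelled here.

**Water** has no datapoint sample; its price is constructed. A household
uses `water_lpd` (default 1.5) litres per person per day for handwashing;
the annual volume is priced at a piped/non-piped weighted unit cost using
the stratum's piped-supply share. Unit costs are supplied directly in 2019
US$ per m³. Because the water price is an assumption rather than a sampled
distribution, it is held fixed in the Monte Carlo by default (sampling can
be enabled with a user-supplied coefficient of variation).

## Uncertainty analysis

Price uncertainty is propagated by Monte Carlo (default 1000 draws): each
iteration draws one pooled I$ mean per sampled category (promotion, HWF,
soap, formative research by default) from its gamma prior and re-prices the
whole model; quantities are never varied (the coverage estimates carry no
published CIs). One draw per category per iteration is applied to *all*
countries: the uncertain object is the pooled mean itself, so draws are
perfectly correlated across countries — independent country draws would
average out and understate total-cost uncertainty. Top-up inherits the
promotion draw, being defined as a fraction of it.

Every cost stream is exactly linear in its category's localised unit price,
so a draw's full-model evaluation reduces to scaling each category's
discounted total by draw/point-mean. This is an exact re-evaluation, not an
approximation, and it keeps 1000 draws effectively instantaneous. The
uncertainty interval is the empirical 2.5th/97.5th percentile pair of the
draw totals, with linear interpolation between order statistics (R's
default type-7 quantile); the point estimate is always the deterministic
run and is never altered by the draws. Contracts checked by the tests:
bit-reproducibility under a fixed seed, interval collapse to the point
estimate as SEs vanish, and interval width scaling as $1/\sqrt{k}$ when all
SEs shrink by $\sqrt{k}$.

## Deterministic scenarios

One-way scenarios re-run the full deterministic model with a single
parameter perturbed, and are shipped as a YAML catalogue
(`inst/extdata/scenarios.yaml`) rather than code so users can extend them.
Price scenarios move a pooled mean to the 2.5th/97.5th percentiles of its
fitted gamma ("high/low plausible values"); discount rate, useful lives and
the top-up fraction get explicit low/high values; the home-made HWF,
economies of scale and the alternative promotion package (excluding
one-to-one activities) are one-sided. Results are oriented so
low ≤ base ≤ high and sorted by swing for tornado plotting.

The economies-of-scale schedule reduces promotion (and top-up), HWF and
soap unit prices by implementation year: 10% off in year 2, then decrements
of 2 percentage points (8% in year 3, 6% in year 4, ...), to a flat 30%
total reduction from year 6 on. The reductions are additive on the year-1
price — multipliers 1.00, 0.90, 0.82, 0.76, 0.72, 0.70 — which is the
reading consistent with "a total of 30%"; compounding multiplicative
decrements would bottom out near 27.4% instead.

## The synthetic data generator

No deposited inputs exist, so the generator emulates the structure the
model assumes and everything downstream is tested against it:

* country populations are drawn lognormal (mean ≈ 24 million, heavy tail)
  with 1–3%/yr exponential growth, split urban/rural with rural-majority
  shares; household sizes are smaller in urban strata;
* service breakdowns are Dirichlet-style draws (rural strata skewed
  towards "no facility") normalised to sum to one; limited-service splits
  centre on 47/10/43;
* economic factors have deflator series from constant country-specific
  inflation (base 2019 = 100) and PPP/exchange-rate ratios drawn in
  (0.24, 0.43), the price-level range implied by the published I$42 soap
  mean localising to roughly US$10–18;
* price datapoints are gamma draws on the I$ scale, then disguised in a
  random country's currency and price year (a third re-expressed in US$)
  so the standardisation path is genuinely exercised; datapoint counts
  default to 14 (promotion), 16 (HWF), 10 (soap) and 5 (formative).

The published anchors are *localised US$ medians per household*, while the
pipeline propagates pooled I$ *means*. The generating gamma's median is
therefore set to anchor/ratio-mid (ratio-mid = the midpoint of the PPP/FX
ratio interval), and the drawn sample is rescaled so its sample mean sits
on the generating gamma's mean. The rescaling preserves the right-skewed
shape and the coefficient of variation; without it, a five-point category's
sample mean wanders ±20% and the fixture would not be calibrated in any
useful sense. The residual, deliberate gap between the fixture's localised
medians and the anchors is the gamma mean/median ratio (≈ +9% at CV 0.5) —
the same mean-versus-median wedge that appears when a costing exercise
pools means but reports medians.

The canonical fixture (`reference_fixture()`, 46 countries, fixed seed) is
generated in code rather than shipped as files, so tests, analysis scripts
and the acceptance checks all see identical inputs with no download. What
the generator does **not** emulate: real JMP/DHS/UN file formats, coverage
trends, urban/rural price differentiation, within-country heterogeneity, or
any specific country — passing tests demonstrate the model's arithmetic and
statistical machinery, not agreement with any real country's costs.

## Numerical choices and problem sizes

* Fractional household counts are kept throughout and rounded only at
  reporting, avoiding order-dependent rounding across 92 strata.
* Reporting rounds billions to 1 decimal, shares to integer percent, and
  US$ millions to 3 significant figures.
* Validation is row-addressed and fails fast; imputation of missing
  service breakdowns (earlier-year value, else LDC average) records its
  provenance and is idempotent.
* The test suite runs the full pipeline on a 3-country fixture (fast
  enough for property loops) and the 46-country reference fixture where
  stock-level realism matters; Monte Carlo contract tests use 500–4000
  draws; parameter-recovery tests use $10^4$ synthetic datapoints.

## Limitations

The model inherits the costing frame's limits: no effectiveness, uptake or
adherence; no capital cost of new water supplies; a single national price
per category; no coverage trend. The cohort-sizing rule under population
growth and the top-up/repeat-year interaction are conventions chosen here
(documented above) — alternative readings change totals by a few percent.
Synthetic results are calibrated to published per-household price anchors
and LDC-like population structure, but absolute totals from the reference
fixture are properties of the fixture, not estimates for any real country
set.
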
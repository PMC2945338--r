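---
title: "Methods: design-based area adjustment and carbon book-keeping"
author: "luccarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design-based area adjustment and carbon book-keeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luccarbon)
```

# Scope

`luccarbon` estimates the terrestrial carbon consequences of land-use change
at a national scale. It couples two methods that are standard in land-change
science but rarely shipped together as tested code:

1. **Design-based area estimation.** A land-change map made from satellite
   imagery misclassifies some area; a stratified accuracy assessment (a
   random sample of map polygons per map class, each checked against
   reference data) lets us *adjust* the mapped class areas and attach
   confidence intervals to them.
2. **Carbon book-keeping.** Given annual rates of forest harvest, clearing
   and afforestation (ha/yr), an accounting model tracks the carbon stocks
   those events commit to the atmosphere or the biosphere — wood products
   that decay over years to a century, slash rotting on site, soil carbon
   lost after conversion and regained after abandonment, and regrowing
   vegetation — and reports the national net flux per year.

The default parameterisation is the Republic of Georgia after the Soviet
collapse, where the observed forest loss is attributed to small-scale
(mostly illegal) logging; but every coefficient and every rate series is an
argument, so the pipeline applies to any region with comparable inputs.

# The stratified area estimator

The input is an error matrix: counts $n_{hc}$ of assessed samples mapped as
stratum $h$ whose reference class is $c$, with per-stratum sample sizes
$n_h$ and mapped areas $A_h$ (total $A_{tot}$). With area weights
$W_h = A_h / A_{tot}$ and per-stratum reference proportions
$p_{hc} = n_{hc}/n_h$, the true-area proportion of class $c$ is estimated
as

$$\hat\phi_c = \sum_h W_h\, p_{hc}, \qquad
  \hat A_{c} = A_{tot}\, \hat\phi_c,$$

with stratified-sampling variance

$$\hat V(\hat\phi_c) = \sum_h W_h^2\, \frac{p_{hc}\,(1-p_{hc})}{n_h - 1},$$

standard error $S(\hat A_c) = A_{tot}\sqrt{\hat V}$, and confidence
interval $\hat A_c \pm m\, S(\hat A_c)$. Three choices deserve comment:

* **Adjusted area as $A_{tot} \times \hat\phi_c$.** The estimator
  multiplies the *total* assessed area by the class proportion, not the
  class's own mapped area. This is the only form under which adjusted areas
  across classes sum to $A_{tot}$, and it is the form that reproduces the
  published Georgian estimates the package uses as a regression anchor.
* **CI multiplier $m = 2$, not 1.96.** The source analysis used a
  half-width of exactly two standard errors; `ci_multiplier` is exposed
  (default 2) so a 1.96 convention is one argument away.
* **Generalised $p_{hc}$.** The estimator is applied per reference class
  rather than only to the change class, which yields user's/producer's
  accuracies, the overall and the area-weighted accuracy from the same
  sweep.

Strata with fewer than two samples are rejected (the variance estimator
divides by $n_h - 1$); map classes excluded from an assessment simply do
not appear in the matrix, and their mapped area is excluded from
$A_{tot}$. A producer's accuracy for a reference class that no assessed
sample belongs to is reported as missing, not zero.

The packaged example is the Georgian assessment: 949 samples over three
strata (forest-to-non-forest change, stable forest, stable non-forest)
with 87/431/431 samples and 6.79 Mha assessed:

```{r table1}
em <- read_error_matrix(system.file("extdata", "georgia_error_matrix.csv",
                                    package = "luccarbon"))
area_report(em)
```

Note the printed per-stratum areas sum to 6,788,407 ha while the source
total is 6,788,387 ha — a 20 ha inconsistency in the original table. At the
precision of the reported estimates the choice does not matter; the package
uses the sum of the per-stratum areas, as the container's invariant
requires.

## Monte-Carlo validation

`truth_spec()` fixes a known confusion structure, `simulate_assessment()`
draws per-stratum multinomial counts at fixed $n_h$ (stratified random
sampling; spatial autocorrelation is deliberately not modelled), and
`coverage_experiment()` checks that the $\pm 2\,SE$ interval covers the
true $\phi$ at its nominal ~95.4% rate, that $\hat\phi$ is unbiased, and
that the analytic SE tracks the Monte-Carlo spread of $\hat\phi$. The test
suite runs this at 2,000 replicates for coverage and 10,000 for the SE
comparison — sizes at which the binomial Monte-Carlo error on coverage
(~0.5%) is well inside the asserted band. The tracked class in those checks
is stable forest ($\phi \approx 0.41$): a proportion for which the normal
approximation underlying the interval is accurate. For the rare change
class ($\phi \approx 0.003$) the dominant variance term is a one-in-431
binomial, and normal-theory intervals for such rare proportions are known
to undercover; that is a property of the interval form itself, not of this
implementation.

# The book-keeping model

The model is an accounting scheme, not a process model: no photosynthesis,
respiration or inter-annual climate variability. Land-use events create
**cohorts** (the hectares affected by one event type in one year), and each
cohort follows deterministic response curves thereafter.

**Event allocation.** Removed vegetation carbon is split between on-site
slash and three wood-product pools — fuelwood released within a year
("1-year pool"), short-lived products decaying at 10%/yr of remaining stock
("10-year"), long-lived products at 1%/yr ("100-year"); slash decays at
4%/yr. The split fractions (harvest: 0.307/0.072/0.531 + 0.09 slash;
clearing: 0.500/0.100/0.070 + 0.33 slash) each sum to one, so allocation
conserves mass exactly.

**Removed density.** Mature forest holds 144 tC/ha of vegetation. A
*clearing* levels the site: the full 144 tC/ha is routed to pools and
slash, and the site never regrows. A *harvest* cuts the site down to the
post-disturbance minimum of 5 tC/ha, so 139 tC/ha is removed and regrowth
restarts from that minimum. This asymmetry is a deliberate mass-balance
choice: the carbon a harvest cohort later re-fixes (5 → 144 tC/ha) then
equals exactly what was removed, making harvest-with-reforestation
carbon-neutral in the long run — the behaviour the model family intends —
while a clearing commits its full vegetation stock. An alternative reading
(all events remove the full mature density) double-counts the residual
5 tC/ha and leaves harvest ~3.5% from neutral at any horizon.
A `biomass_discount` scalar (default 1) can down-weight removals for
partially cleared polygons.

**Regrowth.** The recovery curve is piecewise linear through the three
documented anchors — 5 tC/ha at age 0, 127 tC/ha at 80 years, 144 tC/ha at
100 years, flat thereafter — the simplest monotone form consistent with all
anchors. The functional form between anchors is not documented in the
sources the coefficients derive from, so the curve is pluggable
(`regrowth_curve` coefficient) for sensitivity work. Annual uptake is the
year-over-year density increment (1.525 tC/ha/yr during the first 80
years, 0.85 for the next 20, then 0).

**Soil.** After clearing, soil carbon declines exponentially from
134 tC/ha toward a floor of 107 tC/ha with e-folding time of one third of
the 40-year recovery window, so ~95% of the committed 27 tC/ha loss occurs
within 40 years — capturing the sharp initial release after conversion.
After abandonment, soil recovers linearly from the floor back to 134 tC/ha
over 40 years. The documented "soil C after disturbance" value of
114 tC/ha is stored in the coefficient set but unused by the default
curves: its role (immediate post-event level vs a waypoint) is ambiguous in
the sources, and the two anchors 134 and 107 fully determine the committed
loss. Abandonment cohorts are assumed to start at the post-clearing floor;
if abandoned land in a particular application retains more soil carbon,
the committed uptake is correspondingly smaller and the coefficient set
should be adjusted.

**Annual ordering and signs.** Events occur at year start; decay, soil and
regrowth fluxes are computed within the same year (so the fuelwood pool is
released in the event year itself, and a cohort's age-1 regrowth increment
also lands in that year). Release is positive. Per event type the annual
flux composes as

$$F_{harvest} = P_{1y} + P_{10y} + P_{100y} + Slash - Regrowth,$$
$$F_{clearing} = P_{1y} + P_{10y} + P_{100y} + Slash + Soil_{rel},$$
$$F_{abandon} = -Regrowth - Soil_{upt},$$

and `run_simulation()` reports the national sums per component in Tg C/yr
(1 Tg = $10^6$ tC). The model is exactly linear in area and equivariant
under time shifts; both properties are exploited as test oracles, along
with closed-form committed totals per event (`committed_carbon()`:
+171 tC/ha for clearing, 0 for harvest, −166 tC/ha for abandonment).

```{r single-event}
fx <- run_simulation(constant_series(2000, 2000, clearing_ha = 1),
                     horizon_year = 2500)
sum(fx$net) * 1e6   # tC committed by one cleared hectare; analytic value 171
```

# Scenarios and the Georgia template

`constant_series()`, `linear_ramp()`, `perturb()` and `+` compose rate
series; `georgia_template()` reconstructs a plausible Georgian land-use
history from the documented rules: clearing from 1800 sized so forest
cover falls from 55% to 41% of the 6.97 Mha national area by 1921; managed
harvest from 1850 at half its post-war level until 1945; afforestation
campaigns 1890–1980; and illegal logging, treated as clearing, starting at
independence in 1991 at the annualised remotely sensed change rate
(22,370 ha over a nominal 10-year epoch → 2,237 ha/yr; the epoch length is
a parameter because the underlying scene pairs span 1987–2001).

The archival harvest and afforestation series behind the original analysis
were never published, so three magnitudes are the package's own anchors,
chosen once from the narrative record and exposed as parameters:

* `harvest_peak = 50000` ha/yr for 1946–1965 — consistent with ~37% of the
  ~2.8 Mha forest estate being 41–60 years old in 2006 (regrown over that
  20-year window);
* `harvest_modern = 6000` ha/yr reached by 1980 after the documented rapid
  decline through the 1960s–70s;
* `afforestation_rate = 2000` ha/yr over 1890–1980, an order of magnitude
  above the ~200 ha/yr of recent natural regrowth, reflecting organised
  campaigns.

Because these magnitudes are reconstructions, the template's headline
fluxes are *illustrative*: the test suite asserts only structural
properties of the template (rule compliance, non-negativity, runtime), and
none of the package's quantitative regression anchors depend on it.
Sensitivity of fluxes to the observed logging rate is exactly proportional
(`perturb()` plus linearity), so ±15%/±25% rate experiments need no extra
machinery.

```{r template}
rs <- georgia_template(start = 1850, horizon = 2100)
fx <- run_simulation(rs, horizon_year = 2100)
fx[fx$year %in% c(2004, 2010, 2040), ]
```

# Numerical choices and limitations

* The 100-year-pool share of an allocation is assigned by remainder, so the
  four-way split is exact in floating point; completeness of the area
  estimator ($\sum_c \hat\phi_c = 1$) holds to 1e-9 relative and is tested
  on random matrices.
* Degenerate inputs are legal where science allows: zero-area events
  allocate zero everywhere; a diagonal error matrix returns the mapped
  areas with zero variance and degenerate intervals; a zero rate series
  yields an identically zero flux series.
* Problem sizes in the shipped tests — 2,000/10,000 Monte-Carlo
  replicates, 500-year single-event horizons, a 301-year national template
  — were chosen so each check's Monte-Carlo or truncation error is at
  least threefold smaller than its asserted tolerance; the whole suite
  runs in a few seconds.
* What passing tests do **not** show: the synthetic assessment generator
  draws independent multinomials per stratum, so clustered or spatially
  autocorrelated reference errors — present in real assessments — are
  outside its scope; and the book-keeping model's response curves are
  regional averages, so year-to-year flux anomalies (climate, fire,
  pests) are invisible by construction.
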
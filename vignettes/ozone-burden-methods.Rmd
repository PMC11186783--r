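---
title: "Methods: source-apportioned ozone-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-apportioned ozone-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(o3burden)
```

# The problem

Ground-level ozone is a secondary pollutant: it is formed in the atmosphere
from precursor gases (NOx and volatile organic compounds) and can travel far
from where those precursors were emitted. A national mitigation strategy
therefore controls only part of a country's ozone burden. Quantifying how
much of the ozone-attributable mortality in each region is due to national
emissions, to emissions of other countries, to shipping, or to air entering
the modelled domain from outside (the hemispheric background) requires three
ingredients that this package binds together:

1. a **source-tagged exposure field**: daily maximum 8-hour average (MDA8)
   ozone per grid cell, additively decomposed by source tag;
2. a **health-impact assessment** turning exposure and observed weekly
   all-cause deaths into attributable deaths with uncertainty; and
3. a **model evaluation** layer establishing that the simulated ozone is
   usable at all.

The package works at desk scale on synthetic data whose structure mirrors
the European setting (contiguous regions nested in countries, warm-season
ISO weeks 18--39, five source categories, southward-increasing ozone), so
every stage of the pipeline can be exercised and tested without any
external download.

# The health-impact model

For grid cell $x$ and day $d$, the daily attributable fraction under a
log-linear exposure--response association is

$$\mathrm{AF}(x,d) = 1 - \exp\{-\beta \, \mathrm{O}_3(x,d)\},$$

with $\beta$ the relative-risk coefficient per 1 µg m⁻³ of MDA8 ozone. The
default `beta_er()` is 0.00018 (95% CI 0.00012--0.00024), the meta-analytic
multicountry estimate for all-cause mortality; its bounds are propagated
through the entire chain to give empirical confidence intervals (eCI).

The chain is computed in a fixed order (`hia_burden()`):

1. daily AF per cell;
2. **weekly** arithmetic mean of AF per cell (mortality is observed weekly);
3. **population-weighted** mean over the cells of each region, using only
   the population each cell contributes to that region — a cell on a
   regional boundary never double-counts people;
4. attributable number $\mathrm{AN}(r,w) = N(r,w) \times \mathrm{AF}(r,w)$,
   where $N(r,w)$ are the observed deaths in region $r$ and ISO week $w$;
5. apportionment of AN across source tags;
6. warm-season totals, mortality rates per million, country-to-country
   matrices and national:imported ratios as reporting views.

AN values are kept as real numbers throughout; deaths are rounded to
integers and rates to one decimal only in written reports
(`rate_per_million()` rounds to one decimal, matching the convention of
published rate tables).

## Apportionment rule

The decomposition of AN by source is not uniquely determined by the AF
equation, because AF is (mildly) nonlinear in concentration. We use
**linear concentration shares**: the share of tag $s$ in region $r$, week
$w$ is the population-weighted weekly-mean tagged concentration divided by
the total, and AN is split multiplicatively. This rule is exactly additive
by construction — apportioned parts always sum to the regional AN, at every
aggregation level.

The alternative reads each source's contribution off the curve,
$\mathrm{AF}_s = \mathrm{AF}(C) - \mathrm{AF}(C - C_s)$, normalized to
shares. At observed exposures $\beta C \approx 0.02$, the curve is within
about 1% of linear, so the two rules differ negligibly;
`apportionment_diagnostic()` computes both on any run and reports the
largest share discrepancy (well below 0.5 percentage points in the default
scenario). Linear shares are the default because exact additivity is worth
more than a sub-percent distinction the data cannot support.

## Threshold sensitivity

There is no compelling evidence of a safe ozone threshold, so the default
uses the full exposure range. A sensitivity mode evaluates a threshold $T$
(70 µg m⁻³ is the conventional choice): days with total ozone below $T$ are
**excluded before weekly averaging** and the association is centered at
$T$, i.e. $\mathrm{AF} = 1 - \exp\{-\beta(\mathrm{O}_3 - T)\}$ above it. A
configuration switch (`threshold_mode = "zero"`) instead keeps sub-threshold
days with AF = 0, which gives totals at or below the exclusion mode (the
weekly mean then averages in zeros). Thresholded AF is pointwise below the
full AF, so thresholded totals can only be smaller; in the default synthetic
scenario the total shrinks by a factor of about 2.7.

## Uncertainty

The eCI propagates only the 95% bounds of $\beta$: the chain is re-run with
`beta$low` and `beta$high`. Because AF is monotone in $\beta$, the bounds
bracket the central estimate everywhere, and because AF is concave in
$\beta$, the lower bound can never undershoot the proportional scaling
$\beta_{low}/\beta_{central}$. No resampling of mortality or exposure is
performed — the observed death counts are treated as given, which is the
convention for attributable-burden assessments of this design.

# MDA8 and the availability rule

`mda8_series()` follows the EU-directive convention: each day has 24
candidate 8-hour windows, ending at 01:00 through 24:00 local time, so the
seven earliest windows reach into the previous day. A window qualifies if
at least 6 of its 8 hours are present (its value is the mean of the present
hours); the day's MDA8 is the maximum over qualifying windows. The ≥6/8
within-window rule is a documented regulatory convention, chosen here
because the MDA8 definition itself does not pin it down.

A station-day enters any comparison only with **strictly more than 75%**
hourly availability: 18/24 hours (exactly 75%) fails, 19/24 passes
(`availability_filter()`). Simulated gridded fields are supplied directly
as daily MDA8 and bypass this module, mirroring how chemistry-transport
model output is used.

# The tagged box model

`box_step()` implements the attribution logic of tagged (source-resolved)
photochemistry at toy scale. Ozone and its precursors carry per-source
labels; at each step:

- the chemical regime is diagnosed from the H₂O₂:HNO₃ ratio — below 0.35
  VOC-sensitive, above NOx-sensitive. The tie at exactly 0.35 is classified
  NOx-sensitive (the rule is stated on open intervals; any fixed tie-break
  suffices and this one is documented), and zero HNO₃ (ratio → ∞) is
  NOx-sensitive;
- ozone produced is credited to tags **proportionally to their share of the
  limiting precursor** (NOx under NOx-sensitive, VOC under VOC-sensitive),
  consuming that precursor with a 1:1 toy yield; production is rate-limited
  to the precursor mass available, so no concentration is ever clipped;
- ozone destroyed (first-order chemical loss and deposition) is debited
  proportionally to current tagged ozone, which preserves shares;
- boundary inflow is credited wholly to the boundary (hemispheric) tag.

Production is applied before loss within a step; this ordering is a
documented choice, not a claim about any particular chemistry-transport
implementation. H₂O₂ and HNO₃ are prescribed forcings, not prognostic
species — only their ratio matters to the attribution rule.
`run_tagged_lattice()` chains boxes with a prevailing west→east advective
exchange: boundary air enters at the western edge, so the hemispheric share
decays downwind, the qualitative signature of westerly import.

The box model's role in the package is to supply **ground-truth shares**:
`box_equilibrium()` converges to constant per-tag shares, which can be fed
to the exposure generator; the pipeline must then recover them exactly
(share-linearity of the apportionment makes this an exact identity, tested
at 1e-6 relative).

# Model evaluation

`evaluate_stations()` compares modelled and observed MDA8 at stations that
are rural background and **strictly below 1,000 m** altitude (such stations
have spatial representativeness comparable to a regional model's grid), on
days passing the availability rule. Per station: Pearson $r$,
NMB $= 100\sum(M-O)/\sum O$, NRMSE $= 100\,\mathrm{rmse}/\bar O$, and the
modelling quality indicator

$$\mathrm{MQI} = \mathrm{r.m.s.e.} / (\beta \times \mathrm{r.m.s.}_U),
\qquad \beta = 2,$$

which allows the model--observation difference to be twice the measurement
uncertainty. MQI ≤ 1 is acceptable at a station; the network-level quality
objective is met when at least 90% of stations are acceptable (the boundary
is inclusive: 9 of 10 meets it). The measurement uncertainty
$\mathrm{r.m.s.}_U$ is a per-station input with a constant default of
10 µg m⁻³; the full concentration-dependent uncertainty expansion of the
FAIRMODE guidance is out of scope, but `rms_u` accepts a user function of
the observed series for anyone who wants to supply it.

# The synthetic-data generator

`scenario_config()` fixes the study conditions; the generators are fully
determined by it (identical configs give byte-identical outputs).

- **Grid**: an abstract regular lattice indexed (row, col), row 1
  northernmost; no geodesy — the pipeline's mathematics is
  projection-agnostic.
- **Exposure** (`generate_exposure()`): a latitudinal baseline from
  77 µg m⁻³ (north) to 130 µg m⁻³ (south) — the span of reported national
  means from Finland to Malta — plus a smooth seasonal bump (12 µg m⁻³
  amplitude), an AR(1) synoptic anomaly shared across the grid
  ($\phi = 0.6$, innovation sd 6 µg m⁻³) and per-cell noise (sd 3 µg m⁻³),
  truncated at zero. Totals are split across tags with *constant* shares,
  so the ground truth of every apportionment is known. The default profile
  (national 11.7%, other-European 20.9%, other-in-domain 3.5%, maritime
  7.2%, hemispheric 56.7%) mirrors the reported European mortality-share
  breakdown, making the headline qualitative result — hemispheric dominant,
  imported ≈ 88% — reproducible on defaults. With `expanded = TRUE` the
  other-European share is resolved per source country (fixed seeded
  weights), the form `country_matrix()` requires.
- **Regions** (`generate_region_map()`): raster-order contiguous blocks,
  nested into countries; cell populations log-normal
  (median 2·10⁴, sdlog 0.8).
- **Mortality** (`generate_mortality()`): independent Poisson counts with
  mean population × rate, the standard count model for death tallies; the
  default rate 1.8·10⁻⁴ per person-week reproduces the Eurostat order of
  magnitude (≈ 6.3M warm-season deaths among 530M people over three
  seasons).
- **Observations** (`generate_observations()`): stations on random cells
  with a mix of types and altitudes (0--1,200 m, so the filters have work
  to do). The hourly profile has an 8-hour afternoon plateau at the target
  MDA8 (cell truth + Gaussian noise, default sd 10 µg m⁻³) and a quarter of
  it otherwise; this makes the day's maximum 8-h mean equal the target
  exactly and keeps windows that reach into the previous evening from ever
  exceeding it. Hours are masked missing with a fixed per-station
  probability — the simplest mechanism that exercises the availability
  rule.

What the generator does **not** emulate: real meteorology, emissions or
chemistry; spatially varying source shares (constant shares are what makes
exact recovery testable); heteroscedastic or autocorrelated measurement
error; reporting artefacts in mortality series. Passing tests therefore
demonstrate the pipeline's arithmetic and invariances, not fidelity of any
simulated field to the real European ozone distribution.

# Numerical choices and degenerate inputs

- ISO-8601 week numbering throughout; years are ISO week-based years.
  Partial ISO weeks at data edges are dropped and logged; sub-threshold
  exclusions and unmatched region-weeks are counted in `burden$dropped`.
- Zero-population regions are excluded from burden with a warning; a zero
  imported burden makes the national:imported ratio `Inf` with a message.
- Exposure files are validated on load: fixed columns, non-negativity
  (error names the first offending row), duplicate keys rejected, and an
  optional `tag == "total"` series is additivity-checked at 1e-6 relative
  before being dropped.
- Apportionment rejects share vectors off unity by more than 1e-6; exact
  additivity of the tagged series is asserted at 1e-9 relative in tests.
- The test suite runs the full pipeline on 4×4-cell, 4-week scenarios (and
  one hundred 2×2 randomized ones for the additivity sweep); the default
  12×12 × 3-year scenario is used by the acceptance script. These sizes are
  the package's chosen desk-scale study conditions; all invariants they
  verify are size-independent identities.

# Limitations

Deliberately out of scope: the chemistry-transport modelling system itself
(meteorology, emission inventories, full chemical mechanisms, boundary
conditions), real-geography rasters and GIS ingestion, years-of-life-lost
and economic valuation, chronic-exposure risk, age-stratified or
country-specific coefficients, and any claim that the toy box model
reproduces the numerics of a full tagged chemistry-transport method — it
reproduces the *attribution rules*, which is what the burden pipeline
consumes.
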
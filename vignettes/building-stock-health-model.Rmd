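---
title: "Modelling health and climate impacts of city building-stock heating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling health and climate impacts of city building-stock heating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatburden)
```

## The model

`heatburden` estimates the public-health and climate consequences of how a
city heats its buildings, and how those consequences shift under policy. The
chain is deliberately simple and auditable; every arrow is one function:

```
building stock (m², by cohort/type/heating/renovation state)
  --evolve_stock-->        stock over time (construction, ageing, renovation)
  --heat_demand-->         heating energy (GWh/a, area × specific demand)
  --fuel_use-->            fuel input (MWh/a, mix shares × efficiency)
  --emissions_from_fuel--> CO2 (fossil & total) and PM2.5 (t/a)
  --health_burden-->       exposure (µg/m³), premature deaths, DALY/a
```

All intermediate quantities are long-format *indexed tables*: a `Result`
column plus named index columns (`Time`, `Built`, `Heating`, ...), a unit and
a name. Binary arithmetic inner-joins on shared indices and broadcasts over
indices present in only one operand, so a city can add an extra index (say,
`City_area`) to its own data without touching the model code. Two index
names are reserved: `Iteration` for Monte-Carlo samples and one column per
policy decision.

### Policies as scenario indices

The core model contains no policies. A `decision_table()` declares them
outside the model: each row names a decision, an option, a target input
table, a cell selector and a change (`multiply`, `add`, `replace`). At run
time every targeted table is expanded along a new index whose `"BAU"` level
reproduces the untouched input bit-for-bit; downstream outputs then carry
the full factorial of options automatically (three renovation options × two
fuel options = six scenario columns in every output year). The BAU slice of
a run with decisions equals a run without them to within floating-point
identity — this is asserted in the test suite at 1e-12 relative tolerance.

Two decision-application details are conventions, not physics: when several
rows of one decision hit the same table they apply in row order (so
`multiply`/`add` do not commute with a later `replace`), and an option whose
selector matches nothing is an error rather than a silent no-op, because an
inert policy row almost always indicates a typo in the selector.

### Stock dynamics

The stock is floor area (m²) by construction era (`Built`, decade bins
labelled by start year), building type, heating system and renovation state
(`none`, `windows`, `windows_sheath_tech`, `total_sheath`). Each year:
construction adds new area (era = current decade, unrenovated), an optional
uniform demolition rate removes area (default 0 — demolition is left out of
the standard model), and a renovation transition moves
`rate × eligible area` into the renovated states. Eligibility is
age-gated: unrenovated area whose era start lies more than `age_threshold`
(default 30) years back. Using the era *start* year is the conservative
reading of an age gate on decade-binned cohorts. Renovated area does not
re-enter eligibility within the horizon; a second deep renovation inside
40 years is unrealistic. The renovation rate applies by default to the
still-unrenovated over-threshold area, which makes the unrenovated fraction
of a static, fully-eligible stock decay exactly geometrically — the suite
checks `(1 − r)^k` to 1e-9 — and an alternative base (`"all"` over-threshold
area) is available by flag.

### Energy, fuels, emissions

Heating demand is floor area times a specific demand (kWh/m²/a) by type,
era and renovation state; renovation subtracts a per-depth saving, floored
at 20 kWh/m²/a so a deep renovation of an already-efficient building cannot
go negative. Only heating energy is modelled; non-heating electricity is out
of scope. No degree-day correction is applied between years (demand per m²
is treated as climate-constant); a global scalar can be folded into the
demand table by users who want one.

Fuel mixes are shares per heating type with `Time` anchors, interpolated
linearly between anchors and held constant outside them (linear
interpolation preserves the sum-to-one constraint, which is enforced before
any computation). Emission factors are kg per MWh fuel for `CO2_fossil`
(the regulated "official" quantity: peat counts at 380 kg/MWh, wood counts
at 0), `CO2_total` (wood's direct stack emission of 420 kg/MWh included)
and `PM2.5`. All combustion emissions of district-heat production are
attributed to delivered heat through a conversion-efficiency factor; the
electricity forgone when cogeneration output falls is bought outside the
city and deliberately out of the system boundary. Upstream (life-cycle)
emissions of fuels are likewise out of scope.

### Exposure and burden

Population exposure uses intake fractions (iF): the fraction of emitted
PM2.5 eventually inhaled by the population. The concentration increment of
a source is

&Delta;C = E · iF / (P · BR · 365.25),

with E the emission (µg/a), P the population and BR the breathing rate
(m³/person/day, default 13). Intake fractions are keyed by source archetype
— here the heating type, so a high-stack district-heat plant (small iF) is
distinguished from ground-level residential boilers (larger iF). Per-source
increments are summed before the exposure-response step, since
concentrations add.

The exposure-response function is the standard log-linear relative risk per
10 µg/m³, RR = exp(ln(RR₁₀)·&Delta;C/10), applied about a counterfactual of
0 µg/m³ (the marginal impact of the source); a linear form is available for
cross-checks. Attributable deaths use the population attributable fraction,
deaths = P·M·(RR−1)/RR, and burden is DALY = deaths × YLL per death with the
morbidity (YLD) component fixed at zero: premature mortality is the only
endpoint. YLL per death is a single scalar; age-structured life tables are
out of scope. For the small exposure increments this model produces, the
chain is numerically indistinguishable from its first-order expansion
P·M·ln(RR₁₀)/10·&Delta;C (verified to 1 % in the tests), which is a useful
sanity check against hand calculations.

### Uncertainty and importance

Inputs can be declared uncertain with `input_distribution()` (point, normal,
lognormal, uniform, triangular; optional truncation applied in quantile
space). The *deterministic* mode replaces each distribution by its median
and runs once — the fast mode for everyday scenario comparison. The
*monte_carlo* mode draws one value per iteration per distribution and
attaches an `Iteration` index to the targeted tables; the index then flows
through every join and aggregation into the outputs. One draw is shared
across all selector-matched cells of a distribution, i.e. a distribution
describes a systematic uncertainty of a quantity, which is exactly the thing
a rank-correlation importance analysis ranks.

Two deliberate restrictions keep the propagation honest:

* Distributions may not target the renovation rate or depth shares. Those
  enter the annual stock recursion nonlinearly, so attaching samples to them
  would require evolving the stock once per draw; they are policy levers
  here, varied through the decision table instead.
* For Monte-Carlo work the inputs should be aggregated first (iteration
  count multiplies every table), so `city_template(detail = "coarse")`
  provides a two-era, one-building-type version of each preset whose totals
  match the fine version exactly. The shipped analyses use 1000 iterations,
  the conventional run size for this type of importance analysis.

For the exposure-response function, a `"scale"` distribution multiplies the
log-linear slope (RR₁₀ ↦ RR₁₀^draw) rather than RR₁₀ itself; this keeps the
relative risk on the ≥ 1 branch for any positive draw, which a naive
multiplication would not.

Climate and health outcomes are put on one scale with nominal valuations of
15 €/t CO2 and 50 000 €/DALY, applied to fossil CO2 — the regulated quantity
the assessed policies steer — and to the burden summed over the horizon.
Importance is the absolute Spearman rank correlation (Kendall available)
between each input's draws and the monetized total, computed per
decision-option combination and summarised as min–max ranges. In
*incremental* mode the BAU combination is subtracted per iteration first, so
the correlation measures influence on the policy effect; at BAU itself the
increments are identically zero and the correlation is reported as `NA`
(undefined), never as 0 — the same convention as for any zero-variance
input. Sampling is independent across inputs; no joint correlation
structure is modelled.

## The synthetic cities

Real city bundles of this kind live in municipal registries and are not
shippable, so the package generates synthetic ones that reproduce the
*structure and printed anchors* of two well-documented cases:

* `kuopio_like` — a district-heat dominated Nordic city: 88 % of 5.0 Mm² of
  floor space on the district network, cohorts 1920–2010, heat demand of
  the order of 800 GWh/a, construction of 125 000 m²/a doubling the stock
  by 2050; cogeneration burning 84 % peat / 12 % heavy oil / 4 % wood, with
  a fuel policy moving to 49 % peat / 1 % oil / 50 % wood; renovation at
  3 %/a of >30-year-old buildings (BAU), 4.5 %/a (Active) or BAU-rate with
  total sheath reform (Total); savings spanning 30–100 kWh/m²/a by depth.
* `basel_like` — a Central European city of 8.0 Mm²: half the space heat
  from district heating (waste/wood/gas 50/10/40, policy 50/30/20), the
  rest from gas and oil boilers; stock growing ~20 % by 2030; renovation at
  1 %/a vs 2 %/a, savings 15–60 kWh/m²/a; its "Total" option renovates
  essentially all eligible stock by the horizon end, implemented as a rate
  high enough (8 %/a) to exhaust eligibility, spread over the years rather
  than front-loaded.
* `mini` — one stratum, one fuel, constant stock: the end-to-end output
  equals the one-line closed form in `mini_city_closed_form()`, which the
  acceptance tests check to 1e-9 relative error.

Values that public reports of such cities do not print — PM2.5 and oil/gas/
electricity emission factors, baseline mortality, intake fractions, RR₁₀,
YLL per death, per-class specific demands — are calibration, chosen once so
that outputs land on the printed order-of-magnitude anchors (about 1.5
premature deaths/a attributable to the cogeneration plant, a few tens of
DALY/a citywide, fossil CO2 falling by roughly a third under the fuel switch
with total CO2 nearly unchanged, and mortality declining by roughly ten
percent under the combined policies). They are labelled synthetic throughout
and should be replaced with measured values for any real assessment. Two
calibration choices worth making explicit: new construction enters a
low-energy demand class (50 kWh/m²/a in the Nordic preset) sized so that
efficiency gains roughly cancel stock growth under BAU renovation, and the
wood-chip PM2.5 factor (0.020 kg/MWh) sits below peat's (0.033) —
low-ash biomass in a modern fluidised bed with electrostatic precipitation —
so the fuel switch is a (modest) PM improvement as well as a fossil-CO2 one.

What passing tests on these bundles shows is that the *machinery* is right:
conservation laws, closed forms, scenario algebra, sampling determinism,
correlation behaviour. It does not validate any real city's numbers; with
synthetic inputs the outputs are only as real as the calibration.

## Numerical conventions and limitations

* Joins drop unmatched rows (inner join) and report the count via a
  `message`; a join with an empty result is an error naming the disjoint
  index. Duplicate index tuples are rejected at construction.
* Units are carried as strings and combined naively on arithmetic; unit
  *checking* is advisory (a warning on adding different units), not
  blocking.
* Aggregation never silently drops the `Iteration` index (explicit flag
  required) nor scenario indices (always retained).
* Problem sizes: the deterministic presets run a 41-year horizon with ~10
  cohorts and six scenario combinations in about a second; the Monte-Carlo
  importance analyses use the coarse (two-cohort) bundles at 1000
  iterations, a few minutes on one core. Test-suite property loops use 500
  random stocks for conservation and 10 000 iterations for the central-limit
  check on a one-stratum city.
* Out of scope by design: indoor air quality and thermal comfort, life-cycle
  CO2 of wood fuels, electricity-market compensation effects, atmospheric
  dispersion and chemistry, NOx/SO2, age-stratified DALYs, and spatial
  disaggregation beyond carrying an optional area index.

## A worked run

```{r, message = FALSE}
bundle <- generate_city("kuopio_like")
res <- run_model(bundle, mode = "deterministic")
report_outputs(res, years = 2030)$burden
```

The six rows are the 2030 disease burden under every combination of the
three renovation options and two fuel options; the BAU/BAU cell is the
reference against which the policy benefits are read.
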
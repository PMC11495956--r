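---
title: "Methods: models, parameters and design choices in nectarscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in nectarscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nectarscape` studies how a small area of residential gardens changes the
seasonal nectar budget of a farmland landscape and what that does to
bumblebee colonies. This vignette is the package's account of its own
methods: the models, their assumptions, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical
choices behind the implementation.

## 1. From floral counts to sugar densities

The currency throughout is grams of sucrose-equivalent sugar per square
metre per 24 h. A survey record (one species in one sampling unit on one
date) is converted as

    sugar density = (floral_units / sampled_area) * sugar_per_floral_unit

Farmland sampling units are 1 m² quadrats; garden units are whole gardens,
with the garden's area as `sampled_area` — both flow through the same
formula. Tree and shrub counts taken in a 5 m vertical column are
multiplied by `plant_height / 5` before conversion (`scale_tree_count`).
Unknown species raise an error naming the missing label; a silent zero
would bias whole-habitat budgets downwards.

## 2. The phenology smoother

`fit_phenology` reduces records to per-date means over sampling units
(repeated measurements of the same unit and species are averaged first, so
accidental duplication cannot change the fit) and fits a penalized
thin-plate regression spline of sugar density on day of year, pooling all
sites, with smoothness chosen by generalized cross-validation. Tunables:

* **Basis dimension `k = 20`.** The spring and mid-summer farmland flushes
  have bloom spreads of around 10–14 days; under weekly sampling a smaller
  basis cannot bend fast enough and flattens the spring flush into the
  mid-season. The penalty, not the basis size, controls effective
  smoothness, so a generous basis costs little; sparse monthly designs are
  automatically clamped to `n_dates - 1`.
* **Error family, `family = "auto"`.** Sugar densities are derived from
  counts, so their variance grows with the mean. For densely sampled
  designs (25+ distinct dates) the default is quasi-Poisson (variance
  proportional to the mean, log link): it stops the long zero stretches of
  a farmland season from shrinking the short flushes, which is exactly
  where an identity-link Gaussian fit loses accuracy. With only eight
  monthly garden dates there is too little information to estimate a
  mean-variance scale and a smoothness on the log scale at once, and the
  quasi-Poisson fit can collapse towards a constant; sparse designs
  therefore fall back to a Gaussian fit on the identity scale with
  predictions clipped at zero. Both behaviours can be forced explicitly.
* **Season merging.** Farmland and garden surveys may come from different
  years; curves are merged on a shared day-of-year grid with no year
  adjustment or climate correction. This assumes between-year phenology is
  comparable — reasonable for neighbouring years in one region, and the
  package makes no attempt to verify it.

Curves carry pointwise standard errors and are non-negative by
construction. `normalize_curve` rescales to unit maximum for shape
comparisons; `curve_maxima` counts seasonal peaks with a prominence filter
(default one tenth of the curve maximum) so numerical ripple is not
mistaken for bimodality.

## 3. Landscape budgets and hunger gaps

`aggregate_landscape` multiplies each habitat curve by its area and sums;
standard errors are propagated as the root-sum-square of area-scaled
errors, which assumes the habitat fits are independent (they are separate
models on separate data). Habitats that genuinely produce nothing (arable,
sealed surfaces) may omit a curve; any other positive-area habitat without
a curve is an error.

The budget is computed on a daily grid. Weekly summaries can always be
derived from it, and a daily grid makes the deficit search exactly
equivalent to a brute-force day-by-day comparison, which the tests exploit
as an oracle.

The bee population curve is `colony_density * area * colony_size *
monthly_weight`, summed over species, with monthly activity weights applied
as step functions (the underlying monitoring data are monthly; no
interpolation is invented). The per-bee demand curve is a baseline
requirement with a multiplier over an early-spring window when heavy
founding queens dominate. The shipped defaults — 0.12 g sugar bee⁻¹ day⁻¹,
multiplier 3 over days 60–135, and the colony densities and sizes in
`default_bee_models()` — are implementer-supplied values inside published
bumblebee energetics and census ranges, clearly configuration rather than
measurements; every analysis accepts alternatives.

`find_deficits` returns maximal runs of days with per-bee supply below
requirement. Days with zero bees are excluded upstream (and flagged);
division by zero is never silent.

## 4. The activity ratio

Transect records are filtered by two rules before any rate is computed:
male records are dropped (male foraging and phenology differ from the
females the colonies depend on), and sections primarily farmland but
secondarily garden are dropped entirely as ambiguous. Rates are total
observations divided by total km of unique sections surveyed — sections,
not rows, are the sampling unit, which is also why the bootstrap for the
ratio CI resamples sections. Months with zero farmland survey effort yield
a missing ratio, never infinity. Workers and queens are pooled; a per-caste
breakdown can be had by pre-filtering.

## 5. The synthetic-data generators

The generators provide every input with known ground truth. Design
choices, fixed once:

* **Bloom model.** Each species blooms as a Gaussian kernel in day of year
  (the simplest unimodal phenology); 365-day years, no leap handling.
* **The contrast.** Farmland species (8 by default) are split across
  pasture, woodland, hedgerow and field margin with narrow bloom windows
  (9–14 d spread) clustered into a May and a July flush, so the summed
  farmland curve is bimodal with troughs in early spring and from late
  summer; garden species (56 by default) have peaks spread across
  March–October and wider windows (16–30 d), giving a flat curve.
* **Productivity scales.** Peak densities are rescaled so annual per-m²
  sugar integrals hit habitat targets of 2.5 (pasture), 6 (woodland), 12
  (field margin), 15 (hedgerow) and 22 (garden) g m⁻² yr⁻¹ — magnitudes in
  line with published UK nectar budgets, where linear features are rich
  per unit area, improved pasture is flower-poor, and gardens rival
  hedgerows.
* **Count noise.** Quadrat counts are negative-binomial with dispersion
  (size) 2: field floral counts are strongly clumped and Poisson noise
  would understate their variance. The dispersion is a free parameter of
  the generator, set once at design time.
* **Sampling design.** Farmland weekly, gardens monthly (whole-garden
  counts with areas ~156 m² on average), mirroring the asymmetric designs
  such data really have, so the smoother is tested under realistic
  conditions. A share of woodland records are tall trees counted in the
  5 m column, exercising the height scaling.
* **Landscapes.** Circular, 1 km radius (π km² ≈ 3.14 km²),
  pasture-dominated, with garden patches clustered around a village
  centre. The default 12-landscape set uses `garden_cover_profile()`, a
  synthetic stand-in for the study set's per-landscape garden covers,
  constructed to reproduce its published summary statistics (minimum 0.2%,
  maximum 5.9%, mean exactly 1.9%). Habitats are discretized into tens of
  discrete patches with coordinates snapped to a 10 m grid — patch-level
  rather than cell-level granularity, which is what the simulator's
  foraging kernel needs and keeps a full experiment tractable.
* **Rasters.** Urban cells grow around settlement seeds by weighted
  nearest-distance thresholding, hitting the requested urban fraction
  while forming compact, size-varying settlements; remaining land is
  partitioned into arable/pasture/other blocks.

What the generators do **not** emulate: real taxa and their trait
correlations, spatial autocorrelation of floral abundance within habitats,
weather-driven between-year variation, observer error, and the fine-scale
geometry of linear features. Passing recovery tests on these data shows
the estimators are correct under the stated noise model — not that field
data meet that model.

## 6. The colony simulator

A deliberately simplified, single-species (*Bombus terrestris*-like),
daily-timestep colony model in the tradition of spatially explicit
bee-foraging simulators. It is faithful in structure to that model family —
patch detection falling with distance, crop filling slowed by dilute or
depleted nectar and deep corollas, colony growth emerging from resource
acquisition — while keeping every numeric constant in one documented
configuration (`abm_config()`); it does not attempt to reproduce any
other simulator's numerical output.

The daily cycle: stocks replenish to the day's production (nectar stands
24 h, so stock never exceeds daily production); entities forage in random
order (trips allocated over patches with probability proportional to
`exp(-distance/500 m) × stock`; a trip yields at most one crop of 0.06 g,
less on dilute or depleted patches; patch stocks fall by exactly the sugar
taken, so the tests can assert gram-for-gram conservation); then colony
dynamics run (maintenance, brood maturing after 21 days, brood initiation
from surplus before mid-July, queen rearing after it, starvation death
after 3 consecutive empty-store days). Spring queens emerge
Normal(1 April, 28 d) truncated to the season, must reach a 0.8 g store
within 21 days to found a colony, and their survival fraction is an
endpoint. Foraging effort is discretized as a fixed number of trips per
forager per day (the daily time budget divided by a typical trip) rather
than a per-trip time ledger — a simplification that keeps the day kernel
vectorizable.

Years are annual colony cycles: colonies do not persist over winter; new
queens carry the population into the next year after overwinter losses
(30%), capped by `carryover_cap`. Defaults were chosen to give multi-year
persistence on intact landscapes. The mechanism that separates treatments
is timing: mid-summer farmland nectar is superabundant for any treatment,
so differences arise in early spring (queen founding) and late summer
(queen production), exactly where gardens supply and the
`garden_with_pasture_phenology` treatment — identical annual garden sugar,
mid-summer timing — does not. Treatment effect sizes on these synthetic
landscapes are larger than field-calibrated simulators report, because
conditions are otherwise benign and starvation is the only mortality;
directions, not magnitudes, are the tested claim.

Determinism: one master seed; sub-seeds are derived per (landscape,
treatment, replicate) with a fixed integer recurrence (kept below 2³¹), so
experiment tables are reproducible row by row. Randomness goes through R's
RNG, and generator functions restore the caller's RNG state.

Endpoint contrasts replace a mixed-model analysis with a paired
per-landscape bootstrap: per-landscape means difference against the
baseline treatment, percentage change averaged over landscapes, CI from
resampling landscapes with replacement (10⁴ draws). This honours the
experiment's grouping structure while keeping the whole statistical
procedure inside the package.

The test suite runs the experiment at a reduced size — 12 landscapes × 4
treatments × 5 replicates × 5 years with 200 initial queens and a 200-queen
carryover cap — which resolves the treatment ordering comfortably in a few
minutes on one CPU.

## 7. Garden reach

`distance_to_urban` computes the exact Euclidean distance from every cell
centre to the nearest urban cell centre via a two-pass lower-envelope
distance transform on squared integer distances, so results are
bit-identical to a brute-force all-pairs minimum (the tests assert
`identical()`). Urban cells are within reach at every radius, consistent
with buffers drawn around urban land. Coordinates are planar (a projected
raster is assumed); the raster grid is the approximation scale of the
analysis. Nodata cells are excluded from both numerator and denominator of
every fraction. The radii default to 250/500/750/1000 m, spanning
published small-bee to bumblebee/honeybee foraging ranges. Equating urban
buffers with garden buffers is an assumption (gardens are a large, evenly
spread share of urban land), not a computation this package performs.

## 8. Degenerate inputs and numerical conventions

* Quadrature is trapezoidal on the day grid everywhere, so integral
  identities (aggregation linearity, equal-quantity treatment) hold to
  floating-point precision rather than approximately.
* All-zero survey input yields a flat zero curve with zero error band — a
  valid answer, not an error. All-zero curves cannot be normalized.
* Zero-bee days are excluded (and flagged) before division; zero farmland
  effort gives a missing ratio; zero total supply gives a missing garden
  fraction.
* Dead colonies are inert; energies, counts and stocks are clamped
  non-negative, with starvation tracked explicitly instead of negative
  stores.
* Ties in patch choice are resolved by the multinomial draw itself; no
  ordering of patches is ever load-bearing.

## 9. Known limitations

Nectar only — pollen, nesting sites, weather, predation and disease are
all outside scope, and conditions are otherwise benign, so simulated
effect sizes are upper-bound-like. Activity ratios are raw encounter
rates with no detection-probability model. The garden fraction of supply
is reported on the surveyed season; outside it, farmland supply is ~0 and
the fraction is uninformative. The phenology merge assumes between-year
comparability. The synthetic rasters are statistical stand-ins, not
geography: reach fractions computed on them demonstrate the method, not
national statistics.
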
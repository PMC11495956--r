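# nectarscape

Quantitative tools for a question in pollinator landscape ecology: **do
residential gardens buffer farmland bumblebees against seasonal gaps in
nectar supply?** Farmland habitats (pasture, woodland, hedgerows, field
margins) produce most of a landscape's nectar, but in short intense flushes
driven by a handful of plant species; gardens produce a small, diverse,
temporally flat supply. `nectarscape` implements the full analysis chain
needed to study the consequences — phenology estimation, landscape energy
budgets, behavioural activity ratios, an agent-based colony simulator and a
national-scale accessibility analysis — together with synthetic-data
generators with known ground truth, so every stage can be validated without
field data. It is aimed at pollinator and landscape ecologists.

## What the package computes

**Nectar phenology** (`fit_phenology`). Floral surveys record open floral
units *N* per quadrat; each record is converted to a sugar density
*s = N/A × σ* (g sucrose m⁻² day⁻¹), where *A* is the sampled area and *σ*
the species' sugar production per floral unit per 24 h. Tall trees counted
in a 5 m column are scaled by *h*/5. A penalized thin-plate regression
spline of *s* on day of year, with smoothness chosen by generalized
cross-validation (mgcv), gives each habitat a daily curve with a standard
error band.

**Landscape budget** (`aggregate_landscape`, `per_bee_supply`,
`find_deficits`). Habitat curves are scaled by habitat areas and summed to
the landscape supply *S(d)* (g sugar day⁻¹), divided by the estimated bee
population *B(d)* (colony density × colony size × monthly activity), and
compared with a per-bee daily requirement *R(d)* (with an early-spring queen
multiplier). Maximal runs of days with *S/B < R* are "hunger gaps";
`garden_fraction` tracks the share of *S* supplied by gardens.

**Activity ratio** (`filter_transects`, `garden_farmland_ratio`). From
BeeWalk-style transect records (males and ambiguous farmland/garden
sections excluded), bees km⁻¹ per habitat per month, and the monthly
garden:farmland ratio with a section-level bootstrap CI.

**Colony simulator** (`run_simulation`, `run_experiment`,
`treatment_contrasts`). A daily-timestep, spatially explicit colony model:
spring queens emerge around 1 April, forage on patches (detection decays
exponentially with distance; crop filling is limited by patch nectar
density, corolla depth and depletion; sugar is conserved exactly), found
colonies above an energy threshold; colonies rear brood from surplus,
switch to queen production in mid-July, and starve when stores stay empty.
Four landscape treatments isolate the *quantity* versus the *timing* of
garden nectar: `garden`, `no_garden`, `pasture_replacement` and
`garden_with_pasture_phenology` (identical annual garden sugar,
mid-summer-peaked timing). Endpoint contrasts use a paired per-landscape
bootstrap.

**Garden reach** (`distance_to_urban`, `reach_fractions`). An exact
Euclidean distance transform on a landcover raster gives, for each foraging
radius (250/500/750/1000 m), the fraction of each landcover class within
reach of urban land.

## Worked example

```r
library(nectarscape)

# 1. a synthetic species pool and one season of floral surveys
pool <- gen_species_pool(seed = 1)
surveys <- gen_floral_surveys(pool, quadrats_per_visit = 60, seed = 2)
traits <- species_traits(pool)

# 2. smoothed nectar phenology per habitat
curves <- lapply(names(pool), function(h)
  fit_phenology(surveys$surveys[surveys$surveys$habitat == h, ], traits,
                grid = 65:303))
names(curves) <- names(pool)
curves$garden
#> phenology curve: garden
#>   grid: days 65-303 (239 days)
#>   peak: 0.1326 g m-2 day-1 on day 189
#>   annual integral: 21.53 g m-2

# 3. landscape nectar budget with and without gardens
land <- gen_landscapes(n = 12, seed = 1)
comp <- land[[8]]$composition   # the landscape with 1.9% garden cover
bees <- bee_population(default_bee_models(), comp$cell_area / 1e6,
                       grid = 65:303)
supply <- aggregate_landscape(curves, comp, include_gardens = TRUE)
demand <- demand_curve(grid = supply$day)
find_deficits(per_bee_supply(supply, bees), demand, "with_gardens")
#> nectar deficit report [with_gardens]: 1 interval(s), 10 deficit day(s)
#>   start end max_shortfall
#> 1    65  74     0.2229964
no_gardens <- aggregate_landscape(curves, comp, include_gardens = FALSE)
find_deficits(per_bee_supply(no_gardens, bees), demand, "without_gardens")
#> nectar deficit report [without_gardens]: 3 interval(s), 91 deficit day(s)
#>   start end max_shortfall
#> 1    65  83  0.3578785023
#> 2   152 152  0.0005093667
#> 3   233 303  0.1199999999
```

Read: with a garden share of just 1.9% of the landscape, the simulated
bumblebees face a 10-day early-March deficit; strip the gardens out and the
deficit grows to 91 days, adding a long late-summer hunger gap — the
phenological buffering effect the package is built to quantify. The
`max_shortfall` column is the worst daily shortfall in grams of sugar per
bee within each interval.

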
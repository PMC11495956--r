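Package: nectarscape
Title: Seasonal Nectar Budgets, Bumblebee Activity and Colony Dynamics in
    Farmland-Garden Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how residential gardens buffer seasonal gaps
    ("hunger gaps") in the nectar supply of farmland landscapes. Converts
    floral survey records into smoothed daily nectar-sugar phenology curves
    (penalized regression splines with cross-validated smoothness), aggregates
    habitat curves into landscape-level energy budgets and detects per-bee
    nectar deficits, computes monthly garden:farmland bumblebee activity
    ratios from transect records, runs a simplified agent-based bumblebee
    colony simulator under four garden-manipulation treatments, and measures
    the fraction of land within stated foraging radii of urban areas on a
    landcover raster. A synthetic-data module generates all inputs with known
    ground truth so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
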
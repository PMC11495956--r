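#' Landscape habitat composition
#'
#' Areas of each habitat within one landscape unit cell (1 km2 square or a
#' pi km2 disc).
#'
#' @param landscape_id label.
#' @param areas named numeric vector, habitat -> m2 (>= 0).
#' @param cell_area total cell area in m2; habitat areas must not exceed it.
#' @return an object of class `landscape_composition`.
#' @export
landscape_composition <- function(landscape_id, areas, cell_area = 1e6) {
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("`areas` must be a named vector (habitat -> m2)", call. = FALSE)
  if (any(areas < 0)) stop("areas must be >= 0", call. = FALSE)
  if (sum(areas) > cell_area * (1 + 1e-9))
    stop("habitat areas exceed the cell area", call. = FALSE)
  structure(list(landscape_id = as.character(landscape_id),
                 areas = areas, cell_area = cell_area),
            class = "landscape_composition")
}

#' @export
print.landscape_composition <- function(x, ...) {
  cat(sprintf("landscape %s (%.3g km2):\n", x$landscape_id,
              x$cell_area / 1e6))
  pct <- 100 * x$areas / x$cell_area
  for (h in names(x$areas))
    cat(sprintf("  %-12s %10.0f m2  (%5.2f%%)\n", h, x$areas[[h]], pct[[h]]))
  invisible(x)
}

# Curves must share one day grid for exact pointwise arithmetic.
.common_grid <- function(curves) {
  grids <- lapply(curves, `[[`, "day")
  g <- grids[[1]]
  for (gg in grids)
    if (length(gg) != length(g) || any(gg != g))
      stop("curves must share one day grid (regrid before aggregating)",
           call. = FALSE)
  g
}

#' Aggregate habitat curves to a landscape supply curve
#'
#' Pointwise sum of `area_h * value_h(day)` over habitats, in grams of sugar
#' per day for the whole cell. Standard errors are propagated as the
#' root-sum-square of area-scaled habitat errors (habitat fits are
#' independent).
#'
#' @param curves named list of [phenology_curve()] objects (names are
#'   habitats, all on one grid).
#' @param comp a [landscape_composition()]. Habitats with positive area and
#'   no curve raise an error, except `include_zero` habitats (e.g. sealed
#'   surfaces) which contribute nothing.
#' @param include_gardens include the garden term? (`FALSE` gives the
#'   without-gardens scenario.)
#' @param include_zero habitats allowed to lack a curve (treated as zero
#'   supply); default `c("arable", "urban_other")`.
#' @return a data.frame with columns `day`, `supply` (g sugar day-1 per
#'   cell) and `se`.
#' @export
aggregate_landscape <- function(curves, comp, include_gardens = TRUE,
                                include_zero = c("arable", "urban_other")) {
  stopifnot(inherits(comp, "landscape_composition"))
  habs <- names(comp$areas)[comp$areas > 0]
  if (!include_gardens) habs <- setdiff(habs, "garden")
  need <- setdiff(habs, include_zero)
  miss <- setdiff(need, names(curves))
  if (length(miss) > 0)
    stop("no curve for habitat(s) with positive area: ",
         paste(miss, collapse = ", "), call. = FALSE)
  use <- intersect(habs, names(curves))
  grid <- .common_grid(curves[use])
  supply <- numeric(length(grid))
  var <- numeric(length(grid))
  for (h in use) {
    a <- comp$areas[[h]]
    supply <- supply + a * curves[[h]]$value
    var <- var + (a * curves[[h]]$se)^2
  }
  data.frame(day = grid, supply = supply, se = sqrt(var))
}

#' Daily proportional contribution of gardens to landscape nectar supply
#'
#' @inheritParams aggregate_landscape
#' @return data.frame with columns `day`, `fraction` (garden supply / total
#'   supply; `NA` where total supply is zero), `se` (delta-method error) and
#'   `majority` (`TRUE` where gardens provide more than 50%).
#' @export
garden_fraction <- function(curves, comp,
                            include_zero = c("arable", "urban_other")) {
  tot <- aggregate_landscape(curves, comp, include_gardens = TRUE,
                             include_zero = include_zero)
  g_area <- if ("garden" %in% names(comp$areas))
    comp$areas[["garden"]] else 0
  if (g_area > 0 && !("garden" %in% names(curves)))
    stop("no curve for habitat(s) with positive area: garden", call. = FALSE)
  g <- if (g_area > 0) g_area * curves[["garden"]]$value else
    numeric(nrow(tot))
  g_se <- if (g_area > 0) g_area * curves[["garden"]]$se else
    numeric(nrow(tot))
  frac <- ifelse(tot$supply > 0, g / tot$supply, NA_real_)
  # first-order error, independent garden and non-garden terms
  rest_var <- pmax(0, tot$se^2 - g_se^2)
  se <- ifelse(tot$supply > 0,
               sqrt((1 - frac)^2 * g_se^2 + frac^2 * rest_var) / tot$supply,
               NA_real_)
  data.frame(day = tot$day, fraction = frac, se = se,
             majority = !is.na(frac) & frac > 0.5)
}

#' Bumblebee population model for one species
#'
#' Typical colony density and size plus a monthly activity phenology (step
#' weights in \[0, 1\], maximum 1) describing what share of the peak
#' population is active each month.
#'
#' @param species label.
#' @param colony_density colonies per km2 of farmland.
#' @param colony_size individuals per colony at peak.
#' @param monthly_weights 12 values in \[0, 1\] with max 1.
#' @return object of class `bee_population_model`.
#' @export
bee_population_model <- function(species, colony_density, colony_size,
                                 monthly_weights) {
  if (colony_density <= 0 || colony_size <= 0)
    stop("colony density and size must be > 0", call. = FALSE)
  if (length(monthly_weights) != 12L || any(monthly_weights < 0) ||
      any(monthly_weights > 1) || max(monthly_weights) != 1)
    stop("monthly_weights must be 12 values in [0, 1] with max 1",
         call. = FALSE)
  structure(list(species = species, colony_density = colony_density,
                 colony_size = colony_size,
                 monthly_weights = monthly_weights),
            class = "bee_population_model")
}

#' Default population models for the three most common farmland bumblebees
#'
#' Colony densities and sizes are implementer-supplied defaults within
#' published literature ranges (they are configuration, not measured
#' values); activity phenologies are BeeWalk-like monthly step profiles.
#'
#' @return list of three [bee_population_model()] objects.
#' @export
default_bee_models <- function() {
  list(
    bee_population_model("B_terrestris", colony_density = 30,
                         colony_size = 300,
                         monthly_weights = c(0, 0, .1, .3, .55, .8, 1, .85,
                                             .4, .1, 0, 0)),
    bee_population_model("B_pascuorum", colony_density = 40,
                         colony_size = 120,
                         monthly_weights = c(0, 0, .05, .2, .45, .75, 1, .9,
                                             .5, .15, 0, 0)),
    bee_population_model("B_lapidarius", colony_density = 30,
                         colony_size = 150,
                         monthly_weights = c(0, 0, .05, .25, .5, .8, 1, .8,
                                             .35, .05, 0, 0)))
}

#' Daily bee population curve
#'
#' Sums `colony_density * cell_area * colony_size * weight(month)` over
#' species, with monthly weights applied as step functions at month
#' boundaries.
#'
#' @param models list of [bee_population_model()] objects.
#' @param cell_area_km2 landscape cell area in km2.
#' @param grid day grid (default 1..365).
#' @return data.frame with columns `day` and `bees`.
#' @export
bee_population <- function(models, cell_area_km2 = 1, grid = 1:365) {
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  mon <- month_of_doy(grid)
  bees <- numeric(length(grid))
  for (m in models) {
    stopifnot(inherits(m, "bee_population_model"))
    bees <- bees + m$colony_density * cell_area_km2 * m$colony_size *
      m$monthly_weights[mon]
  }
  data.frame(day = grid, bees = bees)
}

#' Per-bee daily sugar requirement curve
#'
#' A baseline individual requirement (grams sugar per bee per day, covering
#' resting and foraging metabolism) with a multiplier over an early-spring
#' window when founding queens — far heavier than workers — dominate the
#' population.
#'
#' @param grid day grid.
#' @param base_requirement grams sugar per bee per day (default 0.12, an
#'   implementer-supplied value within published bumblebee energetics
#'   ranges).
#' @param spring_queen_multiplier factor applied over the queen window
#'   (default 3).
#' @param queen_window inclusive day-of-year window (default days 60-135,
#'   March to mid-May).
#' @return data.frame with columns `day` and `requirement`; class
#'   `demand_curve`.
#' @export
demand_curve <- function(grid = 1:365, base_requirement = 0.12,
                         spring_queen_multiplier = 3,
                         queen_window = c(60, 135)) {
  if (base_requirement <= 0) stop("requirement must be > 0", call. = FALSE)
  req <- rep(base_requirement, length(grid))
  inq <- grid >= queen_window[1] & grid <= queen_window[2]
  req[inq] <- req[inq] * spring_queen_multiplier
  structure(data.frame(day = grid, requirement = req),
            class = c("demand_curve", "data.frame"))
}

#' Per-bee daily nectar supply
#'
#' Divides the landscape supply curve by the bee population curve. Days with
#' zero bees are excluded from the output and listed in the
#' `excluded_days` attribute — division by zero is never silent.
#'
#' @param supply data.frame from [aggregate_landscape()].
#' @param bees data.frame from [bee_population()] on the same grid.
#' @return data.frame with columns `day`, `per_bee` (g sugar bee-1 day-1)
#'   and `se`.
#' @export
per_bee_supply <- function(supply, bees) {
  if (nrow(supply) != nrow(bees) || any(supply$day != bees$day))
    stop("supply and bee curves must share one day grid", call. = FALSE)
  zero <- bees$bees <= 0
  out <- data.frame(day = supply$day[!zero],
                    per_bee = supply$supply[!zero] / bees$bees[!zero],
                    se = (supply$se %||% rep(0, nrow(supply)))[!zero] /
                      bees$bees[!zero])
  attr(out, "excluded_days") <- supply$day[zero]
  out
}

#' Detect nectar deficit intervals
#'
#' Finds maximal runs of consecutive grid days where per-bee supply falls
#' below the individual daily requirement ("hunger gaps"), with each
#' interval's worst shortfall.
#'
#' @param per_bee data.frame from [per_bee_supply()].
#' @param demand a [demand_curve()] on the same grid.
#' @param scenario label stored with the report (e.g. `"with_gardens"`).
#' @return a `deficit_report`: data.frame with columns `start`, `end`,
#'   `max_shortfall` (g bee-1 day-1), ordered and non-overlapping; the
#'   scenario is kept as an attribute.
#' @export
find_deficits <- function(per_bee, demand, scenario = NA_character_) {
  if (nrow(per_bee) != nrow(demand) || any(per_bee$day != demand$day))
    stop("per-bee and demand curves must share one day grid", call. = FALSE)
  deficit <- per_bee$per_bee < demand$requirement
  runs <- rle(deficit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(start = per_bee$day[starts[keep]],
                    end = per_bee$day[ends[keep]],
                    max_shortfall = vapply(keep, function(i) {
                      idx <- starts[i]:ends[i]
                      max(demand$requirement[idx] - per_bee$per_bee[idx])
                    }, numeric(1)))
  structure(out, class = c("deficit_report", "data.frame"),
            scenario = scenario)
}

#' @export
print.deficit_report <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("nectar deficit report%s: %d interval(s), %d deficit day(s)\n",
              if (is.na(sc)) "" else paste0(" [", sc, "]"), nrow(x),
              if (nrow(x)) sum(x$end - x$start + 1L) else 0L))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}
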
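#' Scale a tree floral count from the 5 m survey column to the whole tree
#'
#' Tree and shrub floral units are counted within a 5 m vertical column
#' above the quadrat; for taller plants the count is multiplied up by
#' `plant_height / 5`.
#'
#' @param floral_units non-negative count(s) from the 5 m column.
#' @param plant_height plant height in metres (>= 5; scaling does not apply
#'   below the column height).
#' @return scaled floral-unit count(s).
#' @export
scale_tree_count <- function(floral_units, plant_height) {
  if (any(floral_units < 0)) stop("floral_units must be >= 0", call. = FALSE)
  if (any(plant_height < 5))
    stop("plant_height must be >= 5 m; no column scaling applies below 5 m",
         call. = FALSE)
  floral_units * plant_height / 5
}

#' Nectar sugar density of survey records
#'
#' Converts each survey record into grams of nectar sugar per m2 per 24 h:
#' the (column-scaled) floral-unit count divided by the sampled area, times
#' the species' mean sugar production per floral unit. Garden records carry
#' the whole garden as `sampled_area`; farmland quadrats 1 m2 — both flow
#' through the same formula.
#'
#' @param records survey data.frame with columns `species_id`,
#'   `floral_units`, `sampled_area`, and optionally `column_capped` and
#'   `plant_height`.
#' @param traits a [species_spec()] table.
#' @return `records` with an added `sugar_density` column (g m-2 day-1).
#' @export
record_sugar_density <- function(records, traits) {
  missing_sp <- setdiff(stats::na.omit(unique(records$species_id)),
                        traits$species_id)
  if (length(missing_sp) > 0)
    stop("species missing from trait table: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (any(records$sampled_area <= 0))
    stop("sampled_area must be > 0", call. = FALSE)
  units <- records$floral_units
  if (!is.null(records$column_capped)) {
    cap <- records$column_capped & !is.na(records$plant_height)
    if (any(cap))
      units[cap] <- scale_tree_count(units[cap], records$plant_height[cap])
  }
  sugar <- traits$sugar_per_floral_unit[match(records$species_id,
                                              traits$species_id)]
  sugar[is.na(records$species_id)] <- 0  # zero-marker rows
  records$sugar_density <- units / records$sampled_area * sugar
  records
}

# Per sampling unit (quadrat or garden) per date: total sugar density; then
# per-date mean with the number of units as fit weight. Pooling all sites
# makes the fit invariant to site splits, and fitting date means with unit
# counts as weights makes it invariant to uniform record duplication.
.daily_means <- function(records, traits) {
  r <- record_sugar_density(records, traits)
  r$day <- doy(r$date)
  r$unit <- as.character(interaction(r$day, r$quadrat %||% r$site,
                                     drop = TRUE))
  r$sp <- ifelse(is.na(r$species_id), ".none", r$species_id)
  # mean over repeated measurements of the same unit x species, then total
  # sugar per unit, then per-date mean weighted by the number of units
  per_rec <- stats::aggregate(sugar_density ~ day + unit + sp, data = r,
                              FUN = mean)
  per_unit <- stats::aggregate(sugar_density ~ day + unit, data = per_rec,
                               FUN = sum)
  agg <- stats::aggregate(sugar_density ~ day, data = per_unit, FUN = mean)
  cnt <- stats::aggregate(sugar_density ~ day, data = per_unit, FUN = length)
  data.frame(day = agg$day, y = agg$sugar_density, w = cnt$sugar_density)
}

#' Fit a smoothed nectar phenology curve
#'
#' Fits a penalized thin-plate regression spline of daily nectar sugar
#' density on day of year, pooling all sites, with the smoothing parameter
#' chosen by generalized cross-validation. Records are first reduced to
#' per-date mean sugar density over sampling units (weighted by the number
#' of units), predictions are clipped at zero, and pointwise standard errors
#' are returned.
#'
#' Count-derived sugar densities have variance that grows with the mean, so
#' for densely sampled (weekly) designs the default error model is
#' quasi-Poisson (variance proportional to the mean, log link), which keeps
#' narrow seasonal flushes from being shrunk towards the long zero
#' stretches. Sparse monthly designs carry too few dates to support both a
#' mean-variance scale and a smoothness estimate on the log scale, so they
#' fall back to a Gaussian fit on the identity scale with predictions
#' clipped at zero. `family` selects either behaviour explicitly.
#'
#' @param records survey records for one habitat (see
#'   [record_sugar_density()] for required columns; a `quadrat` column
#'   identifies sampling units, falling back to `site`).
#' @param traits a [species_spec()] table.
#' @param grid integer day grid for predictions; default spans the surveyed
#'   season.
#' @param k spline basis dimension (default 20 — enough to resolve the
#'   narrow spring and summer farmland flushes under weekly sampling; the
#'   penalty, not the basis size, controls the effective smoothness, and
#'   sparse monthly garden data automatically get a smaller basis).
#' @param family `"auto"` (the default: quasi-Poisson when at least
#'   `dense_dates` distinct dates were surveyed, Gaussian otherwise),
#'   `"gaussian"` (identity link, clipped at zero), `"gaussian_log"`
#'   (Gaussian with log link) or `"quasipoisson"`.
#' @param min_dates minimum number of distinct survey dates required.
#' @param dense_dates date count at which `"auto"` switches to the
#'   quasi-Poisson model.
#' @return a [phenology_curve()].
#' @export
fit_phenology <- function(records, traits, grid = NULL, k = 20,
                          family = c("auto", "gaussian", "gaussian_log",
                                     "quasipoisson"),
                          min_dates = 8, dense_dates = 25) {
  family <- match.arg(family)
  habitat <- unique(records$habitat) %||% NA_character_
  if (length(habitat) > 1)
    stop("fit_phenology expects records from a single habitat", call. = FALSE)
  dm <- .daily_means(records, traits)
  if (nrow(dm) < min_dates)
    stop(sprintf("need at least %d distinct survey dates, got %d",
                 min_dates, nrow(dm)), call. = FALSE)
  if (is.null(grid)) grid <- seq(min(dm$day), max(dm$day))
  if (all(dm$y == 0))
    return(phenology_curve(habitat, grid, rep(0, length(grid)),
                           rep(0, length(grid)), n_obs = nrow(records)))
  if (family == "auto")
    family <- if (nrow(dm) >= dense_dates) "quasipoisson" else "gaussian"
  fam <- switch(family,
                gaussian = stats::gaussian(),
                gaussian_log = stats::gaussian(link = "log"),
                quasipoisson = stats::quasipoisson())
  k_use <- min(k, nrow(dm) - 1)
  fit <- mgcv::gam(y ~ s(day, bs = "tp", k = k_use), data = dm,
                   weights = dm$w, family = fam, method = "GCV.Cp",
                   control = mgcv::gam.control(maxit = 400))
  pr <- mgcv::predict.gam(fit, newdata = data.frame(day = grid),
                          type = "response", se.fit = TRUE)
  phenology_curve(habitat, grid, pmax(0, as.numeric(pr$fit)),
                  pmax(0, as.numeric(pr$se.fit)), n_obs = nrow(records))
}
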
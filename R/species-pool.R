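#' Species trait specification
#'
#' Builds the per-species trait table used throughout the package. Traits
#' carry everything the survey-to-sugar conversion and the colony simulator
#' need: mean nectar sugar production per floral unit per 24 h, a Gaussian
#' bloom window (peak day of year and spread), the floral-unit density at
#' peak bloom, corolla depth and nectar sugar concentration.
#'
#' @param species_id character labels (species are abstract; no attempt is
#'   made to mirror real taxa).
#' @param sugar_per_floral_unit grams sucrose per floral unit per 24 h (> 0).
#' @param bloom_peak_day day of year of peak bloom (1..365).
#' @param bloom_sd spread of the bloom window in days (> 0).
#' @param peak_density floral units per m2 at peak bloom (>= 0).
#' @param corolla_depth corolla depth in mm.
#' @param sugar_concentration grams sucrose per 100 ml nectar.
#'
#' @return a data.frame with one row per species.
#' @export
species_spec <- function(species_id, sugar_per_floral_unit, bloom_peak_day,
                         bloom_sd, peak_density, corolla_depth = 6,
                         sugar_concentration = 50) {
  d <- data.frame(species_id = as.character(species_id),
                  sugar_per_floral_unit = sugar_per_floral_unit,
                  bloom_peak_day = bloom_peak_day,
                  bloom_sd = bloom_sd,
                  peak_density = peak_density,
                  corolla_depth = corolla_depth,
                  sugar_concentration = sugar_concentration,
                  stringsAsFactors = FALSE)
  if (any(d$sugar_per_floral_unit <= 0))
    stop("sugar_per_floral_unit must be > 0", call. = FALSE)
  if (any(d$bloom_peak_day < 1 | d$bloom_peak_day > 365))
    stop("bloom_peak_day must lie in 1..365", call. = FALSE)
  if (any(d$bloom_sd <= 0)) stop("bloom_sd must be > 0", call. = FALSE)
  if (any(d$peak_density < 0)) stop("peak_density must be >= 0", call. = FALSE)
  d
}

#' Habitat profile: a weighted species mix with count overdispersion
#'
#' @param habitat one of `"pasture"`, `"woodland"`, `"hedgerow"`,
#'   `"field_margin"`, `"garden"`, `"arable"`, `"urban_other"`.
#' @param species a [species_spec()] table for this habitat.
#' @param weights relative weights (>= 0, normalized to sum to 1).
#' @param dispersion negative-binomial size parameter for quadrat counts
#'   (> 0; smaller is more overdispersed).
#' @return an object of class `habitat_profile`.
#' @export
habitat_profile <- function(habitat, species, weights = NULL, dispersion = 2) {
  habitats <- c("pasture", "woodland", "hedgerow", "field_margin", "garden",
                "arable", "urban_other")
  habitat <- match.arg(habitat, habitats)
  if (is.null(weights)) weights <- rep(1, nrow(species))
  if (length(weights) != nrow(species) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum to a positive value",
         call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  structure(list(habitat = habitat, species = species,
                 weights = weights / sum(weights), dispersion = dispersion),
            class = "habitat_profile")
}

#' @export
print.habitat_profile <- function(x, ...) {
  cat(sprintf("habitat profile: %s (%d species, dispersion %.3g)\n",
              x$habitat, nrow(x$species), x$dispersion))
  invisible(x)
}

# Gaussian bloom kernel over day-of-year, truncated at 0 (values are already
# non-negative; truncation refers to day range 1..365 on evaluation grids).
bloom_kernel <- function(day, peak, sd) exp(-((day - peak)^2) / (2 * sd^2))

#' True daily sugar curve implied by a habitat profile
#'
#' The noiseless generator mean: for each species, expected floral-unit
#' density `peak_density * weight * kernel(day)` times its sugar production,
#' summed over the mix.
#'
#' @param profile a [habitat_profile()].
#' @param day day grid (default 1..365).
#' @return a [phenology_curve()] with zero standard error.
#' @export
habitat_true_curve <- function(profile, day = 1:365) {
  stopifnot(inherits(profile, "habitat_profile"))
  sp <- profile$species
  v <- numeric(length(day))
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      v <- v + sp$peak_density[i] * profile$weights[i] *
        bloom_kernel(day, sp$bloom_peak_day[i], sp$bloom_sd[i]) *
        sp$sugar_per_floral_unit[i]
    }
  }
  phenology_curve(profile$habitat, day, v)
}

#' Combined trait table of a set of profiles
#'
#' @param profiles list of [habitat_profile()] objects.
#' @return one [species_spec()] table (rows unique by species_id).
#' @export
species_traits <- function(profiles) {
  tab <- do.call(rbind, lapply(profiles, function(p) p$species))
  tab[!duplicated(tab$species_id), , drop = FALSE]
}

# Target annual sugar integrals (g sugar m-2 yr-1) by habitat; magnitudes
# follow published UK nectar budgets: hedgerows and field margins are the
# richest farmland habitats per unit area, improved pasture is flower-poor,
# and gardens rival hedgerows.
.habitat_annual_sugar <- c(woodland = 6, hedgerow = 15, pasture = 2.5,
                           field_margin = 12, garden = 22)

#' Generate a synthetic species pool
#'
#' Draws a species pool encoding the farmland-garden phenology contrast:
#' farmland habitats (pasture, woodland, hedgerow, field margin) are fed by
#' few species with narrow bloom windows clustered into a spring (May) and a
#' mid-summer (July) flush, so their summed curve is bimodal with troughs in
#' early spring and from late summer onwards; the garden habitat is fed by
#' many species with bloom peaks spread from March to October, giving a flat,
#' temporally stable curve. Peak densities are rescaled so each habitat's
#' annual per-m2 sugar integral matches a documented field-realistic target.
#'
#' @param n_farmland number of farmland species, split across the four
#'   farmland habitats (default 8: farmland nectar is supplied by a handful
#'   of species).
#' @param n_garden number of garden species (default 56).
#' @param seed integer seed; output is deterministic given the seed.
#' @param dispersion negative-binomial size for quadrat counts.
#' @return named list of [habitat_profile()] objects (the farmland habitats
#'   that received at least one species, plus `garden`).
#' @export
gen_species_pool <- function(n_farmland = 8, n_garden = 56, seed = 1,
                             dispersion = 2) {
  assert_count(n_farmland, "n_farmland")
  assert_count(n_garden, "n_garden")
  with_seed(seed, {
    farm_habs <- c("woodland", "hedgerow", "pasture", "field_margin")
    # alternate spring (woodland/hedgerow) and summer (pasture/margin) flushes
    hab_of <- rep_len(farm_habs, n_farmland)
    spring <- hab_of %in% c("woodland", "hedgerow")
    peaks <- ifelse(spring, stats::runif(n_farmland, 105, 140),
                    stats::runif(n_farmland, 175, 215))
    farm <- species_spec(
      species_id = sprintf("farm_sp%02d", seq_len(n_farmland)),
      sugar_per_floral_unit = stats::rlnorm(n_farmland, log(2e-3), 0.4),
      bloom_peak_day = round(peaks),
      bloom_sd = stats::runif(n_farmland, 9, 14),
      peak_density = stats::rlnorm(n_farmland, log(40), 0.5),
      corolla_depth = stats::runif(n_farmland, 2, 9),
      sugar_concentration = stats::runif(n_farmland, 30, 60))
    gard <- species_spec(
      species_id = sprintf("gard_sp%02d", seq_len(n_garden)),
      sugar_per_floral_unit = stats::rlnorm(n_garden, log(2e-3), 0.4),
      bloom_peak_day = round(stats::runif(n_garden, 75, 290)),
      bloom_sd = stats::runif(n_garden, 16, 30),
      peak_density = stats::rlnorm(n_garden, log(30), 0.5),
      corolla_depth = stats::runif(n_garden, 2, 12),
      sugar_concentration = stats::runif(n_garden, 25, 60))

    profiles <- list()
    for (h in farm_habs) {
      idx <- which(hab_of == h)
      if (length(idx) == 0L) next
      w <- stats::rgamma(length(idx), 2, 1)
      p <- habitat_profile(h, farm[idx, , drop = FALSE], w, dispersion)
      profiles[[h]] <- .rescale_profile(p, .habitat_annual_sugar[[h]])
    }
    gw <- stats::rgamma(n_garden, 2, 1)
    gp <- habitat_profile("garden", gard, gw, dispersion)
    profiles[["garden"]] <- .rescale_profile(gp, .habitat_annual_sugar[["garden"]])
    profiles
  })
}

# Scale peak densities so the habitat's annual sugar integral hits `target`.
.rescale_profile <- function(profile, target) {
  cur <- curve_integral(habitat_true_curve(profile))
  if (cur > 0) profile$species$peak_density <-
      profile$species$peak_density * target / cur
  profile
}
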
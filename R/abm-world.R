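#' Garden-manipulation treatments
#'
#' The four landscape treatments of the colony-simulation experiment, each a
#' rule applied to garden patches only (non-garden patches are never
#' modified):
#' \describe{
#'   \item{garden}{gardens present as normal (identity).}
#'   \item{no_garden}{gardens removed: garden nectar set to zero.}
#'   \item{pasture_replacement}{gardens replaced with pasture (quantity and
#'     phenology of pasture).}
#'   \item{garden_with_pasture_phenology}{gardens replaced with a habitat of
#'     identical total annual nectar value per m2 but the phenological
#'     pattern of pasture — isolating the timing of garden nectar.}
#' }
#'
#' @return character vector of the four treatment names.
#' @export
abm_treatments <- function() {
  c("garden", "no_garden", "pasture_replacement",
    "garden_with_pasture_phenology")
}

#' Apply a garden treatment to a set of habitat curves
#'
#' Rewrites the garden curve according to the treatment rule; all other
#' habitat curves are returned untouched. Under
#' `garden_with_pasture_phenology` the pasture curve is rescaled by the
#' ratio of annual integrals so every garden patch keeps its original annual
#' per-m2 sugar integral.
#'
#' @param curves named list of [phenology_curve()] objects including
#'   `garden` and (for the replacement treatments) `pasture`.
#' @param treatment one of [abm_treatments()].
#' @return the modified curve list.
#' @export
apply_treatment <- function(curves, treatment = abm_treatments()) {
  treatment <- match.arg(treatment)
  if (treatment == "garden") return(curves)
  g <- curves[["garden"]]
  if (is.null(g)) stop("curve set has no garden curve", call. = FALSE)
  if (treatment == "no_garden") {
    curves[["garden"]] <- phenology_curve("garden", g$day,
                                          rep(0, length(g$day)))
    return(curves)
  }
  p <- curves[["pasture"]]
  if (is.null(p)) stop("treatment needs a pasture curve", call. = FALSE)
  pv <- curve_value(p, g$day)
  if (treatment == "pasture_replacement") {
    curves[["garden"]] <- phenology_curve("garden", g$day, pv)
    return(curves)
  }
  # garden_with_pasture_phenology: pasture shape, garden annual quantity
  ig <- curve_integral(g)
  ip <- trapz(g$day, pv)
  if (ip <= 0)
    stop("pasture curve has zero annual integral; cannot rescale",
         call. = FALSE)
  curves[["garden"]] <- phenology_curve("garden", g$day, pv * ig / ip)
  curves
}

#' Build a simulation world
#'
#' Combines a generated landscape (patches with coordinates and areas), a
#' set of habitat phenology curves and a configuration into the daily state
#' the simulator steps through: per-patch daily production (g sugar per
#' patch per day, curve value times patch area), current stocks, and empty
#' entity arrays sized for the year's queens.
#'
#' @param landscape one element of [gen_landscapes()] output (list with
#'   `patches` and `landscape_id`), or a patch data.frame with columns
#'   `patch_id`, `x_m`, `y_m`, `area_m2`, `habitat`.
#' @param curves named list of [phenology_curve()] objects; habitats without
#'   a curve produce nothing.
#' @param config an [abm_config()].
#' @param treatment one of [abm_treatments()].
#' @return an `abm_world` list.
#' @export
build_world <- function(landscape, curves, config = abm_config(),
                        treatment = "garden") {
  patches <- if (is.data.frame(landscape)) landscape else landscape$patches
  stopifnot(all(c("x_m", "y_m", "area_m2", "habitat") %in% names(patches)))
  curves <- apply_treatment(curves, treatment)
  npatch <- nrow(patches)
  prod <- matrix(0, DAYS_PER_YEAR, npatch)
  for (i in seq_len(npatch)) {
    cv <- curves[[patches$habitat[i]]]
    if (!is.null(cv))
      prod[, i] <- curve_value(cv, seq_len(DAYS_PER_YEAR)) *
        patches$area_m2[i]
  }
  corolla <- patches$corolla_depth %||%
    rep(config$default_corolla_mm, npatch)
  world <- list(
    landscape_id = if (is.data.frame(landscape)) NA_character_ else
      landscape$landscape_id,
    treatment = treatment,
    patches = patches, production = prod, corolla = corolla,
    stock = prod[1, ], day = 1L, config = config,
    entities = NULL)
  class(world) <- "abm_world"
  world
}

# Initialize a year's entities: n queens with Gaussian emergence days
# truncated to the season, random nest-search positions in the 1 km disc,
# and precomputed distance/detection rows against every patch.
init_year_entities <- function(world, n_queens) {
  cfg <- world$config
  n <- as.integer(n_queens)
  px <- world$patches$x_m
  py <- world$patches$y_m
  if (n == 0L) {
    world$entities <- NULL
    return(world)
  }
  th <- stats::runif(n, 0, 2 * pi)
  rr <- 1000 * sqrt(stats::runif(n))
  x <- rr * cos(th); y <- rr * sin(th)
  emerge <- pmin(pmax(round(stats::rnorm(n, cfg$emergence_mean,
                                         cfg$emergence_sd)),
                      cfg$season[1]), cfg$emergence_max)
  dist <- sqrt(outer(x, px, "-")^2 + outer(y, py, "-")^2)
  world$entities <- list(
    state = rep(1L, n), x = x, y = y, energy = rep(cfg$queen_initial_energy_g, n),
    workers = numeric(n), brood = matrix(0, cfg$dev_days, n),
    new_queens = numeric(n), starv = integer(n), search_days = integer(n),
    emergence_day = as.integer(emerge), dist = dist,
    det = exp(-dist / cfg$detection_scale_m))
  world
}

#' @export
print.abm_world <- function(x, ...) {
  cat(sprintf("abm world: landscape %s, treatment %s\n", x$landscape_id,
              x$treatment))
  cat(sprintf("  %d patches; peak daily production %.3g g sugar\n",
              nrow(x$patches), max(rowSums(x$production))))
  if (!is.null(x$entities))
    cat(sprintf("  entities: %d (%d colonies, %d searching queens)\n",
                length(x$entities$state), sum(x$entities$state == 3L),
                sum(x$entities$state == 2L)))
  invisible(x)
}
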
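#' Garden cover of the twelve reference model landscapes
#'
#' Synthetic stand-in for the per-landscape garden covers of the twelve
#' circular farmland study landscapes: a fixed 12-value profile constructed
#' to reproduce the published summary statistics of that set — minimum 0.2%,
#' maximum 5.9% and mean exactly 1.9% garden cover. Values are fractions.
#'
#' @return numeric vector of length 12 (fractions of landscape area).
#' @export
garden_cover_profile <- function() {
  c(0.002, 0.006, 0.008, 0.010, 0.012, 0.014,
    0.016, 0.019, 0.023, 0.027, 0.032, 0.059)
}

# Baseline habitat mix of a Southwest UK mixed farm (fractions of the
# non-garden area): pasture-dominated with arable blocks, some woodland and
# narrow linear features.
.base_landscape_mix <- c(pasture = 0.48, arable = 0.285, woodland = 0.08,
                         hedgerow = 0.022, field_margin = 0.016,
                         urban_other = 0.117)

# Patches per habitat used when discretizing a landscape.
.patches_per_habitat <- c(pasture = 10, arable = 8, woodland = 3,
                          hedgerow = 10, field_margin = 8, garden = 8,
                          urban_other = 3)

# Uniform points in a disc of radius r, snapped to a 10 m grid.
.disc_points <- function(n, r, cx = 0, cy = 0) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  data.frame(x = round((cx + rr * cos(th)) / 10) * 10,
             y = round((cy + rr * sin(th)) / 10) * 10)
}

#' Generate circular model landscapes
#'
#' Builds `n` circular landscapes of 1 km radius (area pi km2, about
#' 3.14 km2) with a pasture-dominated habitat mix, a stated garden cover,
#' and discrete patches with coordinates. Garden patches are clustered
#' around a village centre, mimicking the hamlets embedded in real farmland;
#' other habitats are scattered across the disc. Habitat areas sum exactly
#' to the landscape area.
#'
#' @param n number of landscapes.
#' @param garden_cover vector of garden cover fractions (recycled to length
#'   `n`); default [garden_cover_profile()] — the reference profile with mean
#'   1.9%.
#' @param garden_cover_range optional length-2 fraction pair; when given,
#'   covers are drawn uniformly in this range instead.
#' @param seed integer seed.
#' @return list of `n` landscapes, each a list with `landscape_id`,
#'   `composition` (a [landscape_composition()]), `patches` (data.frame:
#'   patch_id, x_m, y_m, area_m2, habitat) and `garden_cover`.
#' @export
gen_landscapes <- function(n = 12, garden_cover = garden_cover_profile(),
                           garden_cover_range = NULL, seed = 1) {
  assert_count(n, "n")
  radius <- 1000
  cell_area <- pi * radius^2
  with_seed(seed, {
    if (!is.null(garden_cover_range)) {
      if (length(garden_cover_range) != 2L ||
          garden_cover_range[1] < 0 || garden_cover_range[2] > 1 ||
          garden_cover_range[1] > garden_cover_range[2])
        stop("garden_cover_range must be an ordered pair within [0, 1]",
             call. = FALSE)
      garden_cover <- stats::runif(n, garden_cover_range[1],
                                   garden_cover_range[2])
    }
    garden_cover <- rep_len(garden_cover, n)
    lapply(seq_len(n), function(i) {
      g <- garden_cover[i]
      jit <- .base_landscape_mix * stats::rlnorm(length(.base_landscape_mix),
                                                 0, 0.1)
      frac <- jit / sum(jit) * (1 - g)
      areas <- c(frac, garden = g) * cell_area
      # discretize into patches
      village <- .disc_points(1, 600)
      rows <- list()
      for (h in names(areas)) {
        if (areas[[h]] <= 0) next
        k <- .patches_per_habitat[[h]]
        w <- stats::rgamma(k, 3, 1)
        a <- areas[[h]] * w / sum(w)
        pts <- if (h == "garden")
          .disc_points(k, 150, village$x, village$y)
        else .disc_points(k, radius - 50)
        rows[[h]] <- data.frame(
          patch_id = sprintf("L%02d_%s_%02d", i, h, seq_len(k)),
          x_m = pts$x, y_m = pts$y, area_m2 = a, habitat = h,
          stringsAsFactors = FALSE)
      }
      list(landscape_id = sprintf("L%02d", i),
           composition = landscape_composition(sprintf("L%02d", i), areas,
                                               cell_area),
           patches = do.call(rbind, rows),
           garden_cover = g)
    })
  })
}

#' Generate a clustered synthetic landcover raster
#'
#' Urban cells are grown around a set of settlement seed points (nearest
#' weighted-distance thresholding, so settlements form compact blobs of
#' varying size); the remaining land is partitioned into arable, pasture and
#' other blocks around a second set of seeds. A stand-in for a national
#' landcover map with scattered towns and villages.
#'
#' @param size raster side length in pixels (or length-2 rows/cols).
#' @param resolution metres per pixel.
#' @param urban_fraction target fraction of cells that are urban, in \[0, 1\].
#' @param clustering number of settlement seeds (fewer seeds give larger,
#'   more clustered settlements).
#' @param seed integer seed.
#' @return a [landcover_raster()] with classes urban/arable/pasture/other.
#' @export
gen_landcover_raster <- function(size = 200, resolution = 25,
                                 urban_fraction = 0.08, clustering = 8,
                                 seed = 1) {
  if (urban_fraction < 0 || urban_fraction > 1)
    stop("urban_fraction must lie in [0, 1]", call. = FALSE)
  nr <- size[1]
  nc <- if (length(size) > 1) size[2] else size[1]
  with_seed(seed, {
    xy <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    k <- max(1L, round(clustering))
    sr <- stats::runif(k, 1, nr)
    sc <- stats::runif(k, 1, nc)
    sw <- stats::rlnorm(k, 0, 0.6)  # settlement size weights
    score <- rep(Inf, nr * nc)
    for (j in seq_len(k)) {
      d <- sqrt((xy$row - sr[j])^2 + (xy$col - sc[j])^2) / sw[j]
      score <- pmin(score, d)
    }
    cls <- integer(nr * nc)
    n_urban <- round(urban_fraction * nr * nc)
    if (n_urban > 0)
      cls[order(score)[seq_len(n_urban)]] <- 1L
    # rural blocks around coarser seeds
    m <- 25L
    br <- stats::runif(m, 1, nr); bc <- stats::runif(m, 1, nc)
    blab <- sample(c(2L, 3L, 4L), m, replace = TRUE,
                   prob = c(0.40, 0.45, 0.15))
    best <- rep(Inf, nr * nc); bcls <- rep(4L, nr * nc)
    for (j in seq_len(m)) {
      d <- (xy$row - br[j])^2 + (xy$col - bc[j])^2
      upd <- d < best
      best[upd] <- d[upd]; bcls[upd] <- blab[j]
    }
    cls[cls == 0L] <- bcls[cls == 0L]
    landcover_raster(matrix(cls, nr, nc), resolution,
                     class_map = c(`1` = "urban", `2` = "arable",
                                   `3` = "pasture", `4` = "other"))
  })
}
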
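# Shared fixture builders; everything is generated in code at test time.

# Tiny two-species trait table with round numbers for hand computation.
toy_traits <- function() {
  species_spec(species_id = c("spA", "spB"),
               sugar_per_floral_unit = c(0.002, 0.01),
               bloom_peak_day = c(120, 200),
               bloom_sd = c(20, 25),
               peak_density = c(50, 10))
}

# A smooth single-species profile whose truth curve a spline can represent.
smooth_profile <- function(habitat = "pasture", peak = 180, sd = 30,
                           density = 40, sugar = 0.002) {
  habitat_profile(habitat,
                  species_spec("spS", sugar, peak, sd, density),
                  weights = 1)
}

# Noiseless weekly records that exactly trace a profile's truth curve:
# one 1 m2 quadrat per date whose count equals the expected density.
noiseless_records <- function(profile, dates = seq(as.Date("2017-03-06"),
                                                   as.Date("2017-10-30"),
                                                   by = 7)) {
  sp <- profile$species
  rows <- lapply(as.list(dates), function(dte) {
    d <- as.POSIXlt(dte)$yday + 1
    mu <- sp$peak_density * profile$weights *
      exp(-((d - sp$bloom_peak_day)^2) / (2 * sp$bloom_sd^2))
    data.frame(site = "farm1", habitat = profile$habitat, date = dte,
               quadrat = "q1", species_id = sp$species_id,
               floral_units = mu, sampled_area = 1,
               column_capped = FALSE, plant_height = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Minimal single-patch landscape for simulator unit tests.
one_patch_landscape <- function(area = 1e4, habitat = "garden",
                                x = 0, y = 0) {
  data.frame(patch_id = "p1", x_m = x, y_m = y, area_m2 = area,
             habitat = habitat, stringsAsFactors = FALSE)
}

# Flat curve: constant value over the whole year.
flat_curve <- function(habitat, value) {
  phenology_curve(habitat, 1:365, rep(value, 365))
}

# Brute-force deficit scan: the daily comparison oracle.
brute_deficits <- function(per_bee, demand) {
  below <- per_bee$per_bee < demand$requirement
  out <- NULL
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(
        start = per_bee$day[i], end = per_bee$day[j],
        max_shortfall = max(demand$requirement[i:j] - per_bee$per_bee[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      max_shortfall = numeric(0))
  out
}

# Brute-force distance-to-urban oracle in metres (O(cells x urban)).
brute_distance <- function(raster) {
  cls <- raster$classes
  nr <- nrow(cls); nc <- ncol(cls)
  urb <- which(cls == 1L)
  ur <- (urb - 1L) %% nr + 1L
  uc <- (urb - 1L) %/% nr + 1L
  d <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d[i, j] <- sqrt(min((i - ur)^2 + (j - uc)^2))
    }
  }
  d * raster$resolution
}

# Independent trapezoid quadrature for cross-checks.
trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
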
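#' Ground-truth container for synthetic datasets
#'
#' Bundles the noiseless quantities a generator drew its data from, so
#' recovery tests can compare estimates against truth.
#'
#' @param true_curves named list of per-habitat [phenology_curve()] objects.
#' @param true_ratio_profile data.frame of monthly garden:farmland activity
#'   ratios, or `NULL`.
#' @param landscape_specs list of per-landscape compositions, or `NULL`.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_curves = NULL, true_ratio_profile = NULL,
                            landscape_specs = NULL) {
  if (!is.null(true_curves)) {
    for (cv in true_curves) {
      stopifnot(inherits(cv, "phenology_curve"))
      if (any(cv$value < 0)) stop("true curves must be non-negative",
                                  call. = FALSE)
    }
  }
  structure(list(true_curves = true_curves,
                 true_ratio_profile = true_ratio_profile,
                 landscape_specs = landscape_specs),
            class = "synthetic_truth")
}

#' Default survey schedules
#'
#' Farmland habitats are surveyed weekly from March to October (the 2017
#' field season); gardens once per calendar month over the same window (the
#' 2019 season). The asymmetric design is deliberate: the smoother must cope
#' with dense farmland and sparse garden sampling.
#'
#' @param profiles list of [habitat_profile()] objects.
#' @return named list of Date vectors, one per habitat.
#' @export
default_survey_schedule <- function(profiles) {
  habs <- vapply(profiles, function(p) p$habitat, character(1))
  sched <- list()
  for (h in habs) {
    if (h == "garden") {
      sched[[h]] <- as.Date(sprintf("2019-%02d-15", 3:10))
    } else {
      sched[[h]] <- seq(as.Date("2017-03-06"), as.Date("2017-10-30"), by = 7)
    }
  }
  sched
}

#' Generate synthetic floral survey records
#'
#' Simulates quadrat floral-unit counts for each habitat on its survey
#' schedule. The expected count of species *s* in a 1 m2 quadrat on day *d*
#' is `peak_density_s * weight_s * exp(-(d - peak_s)^2 / (2 sd_s^2))`; counts
#' are drawn negative-binomial around that mean (quadrat counts are clumped,
#' so Poisson noise would be too tame). Garden sampling units are whole
#' gardens: counts are totals over a garden's area and `sampled_area` is that
#' area. A share of woodland records are tall trees counted only in the 5 m
#' column, with `plant_height` recorded so the tree-column scaling rule is
#' exercised downstream.
#'
#' @param profiles list of [habitat_profile()] objects (see
#'   [gen_species_pool()]).
#' @param schedule named list of survey Date vectors per habitat; each
#'   habitat's dates must fall in one calendar year. Default
#'   [default_survey_schedule()].
#' @param quadrats_per_visit farmland quadrats surveyed per habitat per visit
#'   (split over three farm sites); default 60 (six 50 m transects of ten
#'   1 m2 quadrats).
#' @param n_gardens number of gardens surveyed each month (default 59).
#' @param seed integer seed.
#' @param tree_fraction share of woodland records treated as tall trees.
#' @return list with elements `surveys` (data.frame: site, habitat, date,
#'   quadrat, species_id, floral_units, sampled_area, column_capped,
#'   plant_height) and `truth` (a [synthetic_truth()]).
#' @export
gen_floral_surveys <- function(profiles, schedule = default_survey_schedule(profiles),
                               quadrats_per_visit = 60, n_gardens = 59,
                               seed = 1, tree_fraction = 0.2) {
  assert_count(quadrats_per_visit, "quadrats_per_visit")
  if (length(schedule) == 0L || any(vapply(schedule, length, 1L) == 0L))
    stop("schedule must contain at least one date per habitat", call. = FALSE)
  for (h in names(schedule)) {
    yrs <- unique(format(schedule[[h]], "%Y"))
    if (length(yrs) > 1L)
      stop(sprintf("schedule for %s spans more than one calendar year", h),
           call. = FALSE)
  }
  habs <- vapply(profiles, function(p) p$habitat, character(1))
  names(profiles) <- habs
  out <- with_seed(seed, {
    rows <- list()
    for (h in habs) {
      p <- profiles[[h]]
      sp <- p$species
      dates <- schedule[[h]]
      if (is.null(dates)) next
      for (dte in as.list(dates)) {
        d <- doy(dte)
        mu1 <- sp$peak_density * p$weights *
          bloom_kernel(d, sp$bloom_peak_day, sp$bloom_sd)
        nsp <- nrow(sp)
        if (h == "garden") {
          areas <- pmin(pmax(stats::rnorm(n_gardens, 156.4, 75), 31.3), 407.7)
          # one row per garden x species, counts over the whole garden area
          g <- rep(seq_len(n_gardens), each = nsp)
          mu <- rep(mu1, times = n_gardens) * areas[g]
          cnt <- stats::rnbinom(length(mu), size = p$dispersion, mu = mu)
          cnt[mu == 0] <- 0L
          rows[[length(rows) + 1L]] <- data.frame(
            site = sprintf("garden%02d", g), habitat = h, date = dte,
            quadrat = sprintf("g%02d", g),
            species_id = rep(sp$species_id, times = n_gardens),
            floral_units = cnt, sampled_area = areas[g],
            column_capped = FALSE, plant_height = NA_real_,
            stringsAsFactors = FALSE)
        } else {
          nq <- quadrats_per_visit
          site <- sprintf("farm%d", rep_len(1:3, nq))
          q <- rep(seq_len(nq), each = nsp)
          tree <- h == "woodland" & stats::runif(nq * nsp) < tree_fraction
          hgt <- ifelse(tree, stats::runif(nq * nsp, 6, 18), NA_real_)
          mu <- rep(mu1, times = nq)
          mu <- ifelse(tree, mu * 5 / hgt, mu)
          cnt <- stats::rnbinom(length(mu), size = p$dispersion, mu = mu)
          cnt[mu == 0] <- 0L
          rows[[length(rows) + 1L]] <- data.frame(
            site = site[q], habitat = h, date = dte,
            quadrat = sprintf("%s_q%03d", site[q], q),
            species_id = rep(sp$species_id, times = nq),
            floral_units = cnt, sampled_area = 1, column_capped = tree,
            plant_height = hgt, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  curves <- lapply(profiles, habitat_true_curve)
  list(surveys = out, truth = synthetic_truth(true_curves = curves))
}

#' Default monthly garden:farmland activity ratio profile
#'
#' High in early spring and late summer (when farmland nectar is scarce) and
#' near parity in mid-summer.
#'
#' @return data.frame with columns `month` (3..10) and `ratio`.
#' @export
default_ratio_profile <- function() {
  data.frame(month = 3:10,
             ratio = c(2.5, 2.2, 1.5, 1.1, 1.0, 4, 6, 8))
}

# Monthly relative bumblebee activity (BeeWalk-like seasonal profile).
.monthly_activity <- c(0, 0, 0.12, 0.3, 0.55, 0.8, 1, 0.85, 0.4, 0.1, 0, 0)

#' Generate synthetic bumblebee transect records
#'
#' Draws BeeWalk-shaped section records: farmland counts are Poisson with a
#' per-km encounter rate scaled by monthly activity; garden counts use the
#' same rate times the true monthly garden:farmland ratio. Male records and
#' ambiguous sections (primary farmland, secondary garden) are included so
#' downstream filters have work to do.
#'
#' @param true_ratio_profile data.frame with columns `month`, `ratio`
#'   (default [default_ratio_profile()]).
#' @param effort named list: km of transect per habitat per month, e.g.
#'   `list(farmland = 61.6, garden = 21)` (defaults split the published 493
#'   and 168 km evenly over the 8 survey months).
#' @param species species labels and their peak per-km encounter rates.
#' @param seed integer seed.
#' @param section_km nominal section length in km.
#' @param male_fraction expected male records as a share of female records.
#' @param ambiguous_fraction share of farmland sections flagged secondarily
#'   garden (to be removed by the filter).
#' @return list with `records` (data.frame: section_id, date,
#'   primary_habitat, secondary_habitat, length_km, species, caste, count)
#'   and `truth` (a [synthetic_truth()] carrying the ratio profile).
#' @export
gen_transect_records <- function(true_ratio_profile = default_ratio_profile(),
                                 effort = list(farmland = 493 / 8,
                                               garden = 168 / 8),
                                 species = c(B_terrestris = 2, B_pascuorum = 1.5,
                                             B_lapidarius = 1, B_pratorum = 0.8),
                                 seed = 1, section_km = 1,
                                 male_fraction = 0.1,
                                 ambiguous_fraction = 0.05) {
  if (any(true_ratio_profile$ratio <= 0))
    stop("true ratios must be > 0", call. = FALSE)
  if (any(unlist(effort) <= 0)) stop("effort must be > 0", call. = FALSE)
  records <- with_seed(seed, {
    blocks <- list()
    sid0 <- 0L
    nsp <- length(species)
    for (m in true_ratio_profile$month) {
      ratio <- true_ratio_profile$ratio[true_ratio_profile$month == m]
      act <- .monthly_activity[m]
      date <- as.Date(sprintf("2018-%02d-10", m))
      for (habp in c("farmland", "garden")) {
        nsec <- max(1L, round(effort[[habp]] / section_km))
        len <- section_km * stats::runif(nsec, 0.7, 1.3)
        ambiguous <- habp == "farmland" &
          stats::runif(nsec) < ambiguous_fraction
        sid <- sid0 + seq_len(nsec)
        sid0 <- sid0 + nsec
        # one row per section x species x caste
        s_idx <- rep(seq_len(nsec), each = nsp)
        rate <- rep(unname(species), times = nsec) * act *
          (if (habp == "garden") ratio else 1) * len[s_idx]
        n_w <- stats::rpois(length(rate), rate)
        n_q <- stats::rpois(length(rate), 0.15 * rate * (m <= 5))
        n_m <- stats::rpois(length(rate), male_fraction * rate * (m >= 7))
        blocks[[length(blocks) + 1L]] <- data.frame(
          section_id = rep(sprintf("sec%05d", sid[s_idx]), 3),
          date = date,
          primary_habitat = habp,
          secondary_habitat = rep(ifelse(ambiguous[s_idx], "garden",
                                         NA_character_), 3),
          length_km = rep(len[s_idx], 3),
          species = rep(names(species), times = 3 * nsec),
          caste = rep(c("worker", "queen", "male"), each = nsp * nsec),
          count = c(n_w, n_q, n_m),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, blocks)
  })
  list(records = records,
       truth = synthetic_truth(true_ratio_profile = true_ratio_profile))
}
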
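#' Run the colony simulator on one landscape
#'
#' Simulates `config$years` years of daily bumblebee colony dynamics.
#' Year 1 starts with `config$init_queens` hibernated queens emerging around
#' 1 April; surviving queens found colonies, colonies grow on the
#' landscape's nectar, and new queens produced after mid-summer carry the
#' population (after overwinter losses, capped at `carryover_cap`) into the
#' next year. Five endpoints are recorded per year and averaged.
#'
#' @param landscape one element of [gen_landscapes()] output.
#' @param curves named list of habitat [phenology_curve()] objects.
#' @param treatment one of [abm_treatments()].
#' @param config an [abm_config()].
#' @param seed integer seed; results are deterministic given the seed.
#' @return a `sim_result` list: `summary` (named means over years of
#'   max_colonies, total_bees, new_queens, spring_queen_survival,
#'   colony_density), per-year vectors, `monthly_colony_density` (years x 12
#'   matrix, colonies per km2 on the 15th of each month), `years`, `seed`,
#'   `treatment`, `landscape_id`.
#' @export
run_simulation <- function(landscape, curves, treatment = "garden",
                           config = abm_config(), seed = 1) {
  world0 <- build_world(landscape, curves, config, treatment)
  cfg <- config
  area_km2 <- if (!is.data.frame(landscape) &&
                  !is.null(landscape$composition))
    landscape$composition$cell_area / 1e6 else pi
  season <- cfg$season[1]:cfg$season[2]
  mids <- mid_month_doy()
  yrs <- cfg$years
  max_col <- tot_bees <- new_q <- surv <- numeric(yrs)
  dens <- matrix(0, yrs, 12)
  with_seed(seed, {
    n_queens <- cfg$init_queens
    for (yr in seq_len(yrs)) {
      if (n_queens == 0L) next  # extinct: all endpoints stay zero
      world <- init_year_entities(world0, n_queens)
      ent <- world$entities
      emerged <- 0
      founded <- 0
      queens_prod <- 0
      matured <- 0
      peak <- 0
      for (day in season) {
        wake <- ent$state == 1L & ent$emergence_day <= day
        if (any(wake)) {
          ent$state[wake] <- 2L
          emerged <- emerged + sum(wake)
        }
        world$entities <- ent
        world <- replenish(world, day)
        world <- daily_forage(world)
        world <- daily_colony_update(world)
        ent <- world$entities
        ctr <- world$last_counters
        founded <- founded + ctr[["founded"]]
        matured <- matured + ctr[["matured"]]
        queens_prod <- queens_prod + ctr[["queens_produced"]]
        ncol_alive <- sum(ent$state == 3L)
        peak <- max(peak, ncol_alive)
        m <- match(day, mids)
        if (!is.na(m)) dens[yr, m] <- ncol_alive / area_km2
      }
      max_col[yr] <- peak
      tot_bees[yr] <- matured + queens_prod
      new_q[yr] <- queens_prod
      surv[yr] <- if (emerged > 0) 100 * founded / emerged else 0
      n_queens <- min(round(queens_prod * cfg$overwinter_survival),
                      cfg$carryover_cap)
    }
  })
  structure(list(
    summary = c(max_colonies = mean(max_col), total_bees = mean(tot_bees),
                new_queens = mean(new_q), spring_queen_survival = mean(surv),
                colony_density = mean(rowMeans(dens[, 3:10, drop = FALSE]))),
    max_colonies_per_year = max_col, total_bees_per_year = tot_bees,
    new_queens_per_year = new_q, spring_queen_survival = surv,
    monthly_colony_density = dens, years = yrs, seed = seed,
    treatment = treatment,
    landscape_id = if (is.data.frame(landscape)) NA_character_ else
      landscape$landscape_id),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulation result: landscape %s, treatment %s, %d year(s)\n",
              x$landscape_id, x$treatment, x$years))
  print(round(x$summary, 2))
  invisible(x)
}

#' Run the full landscape-treatment experiment
#'
#' Full factorial over landscapes, treatments and replicate runs, each with
#' an independently derived sub-seed, returning a tidy table of per-run
#' endpoint means.
#'
#' @param landscapes list from [gen_landscapes()].
#' @param curves named list of habitat [phenology_curve()] objects.
#' @param treatments treatments to run (default all four).
#' @param reps replicate runs per landscape-treatment cell.
#' @param config an [abm_config()].
#' @param seed master seed; sub-seeds are derived per (landscape, treatment,
#'   rep).
#' @return data.frame: landscape, treatment, rep, seed, max_colonies,
#'   total_bees, new_queens, spring_queen_survival, colony_density.
#' @export
run_experiment <- function(landscapes, curves, treatments = abm_treatments(),
                           reps = 20, config = abm_config(), seed = 1) {
  assert_count(reps, "reps")
  rows <- list()
  for (li in seq_along(landscapes)) {
    for (ti in seq_along(treatments)) {
      for (ri in seq_len(reps)) {
        s <- derive_seed(seed, li, ti, ri)
        res <- run_simulation(landscapes[[li]], curves, treatments[ti],
                              config, seed = s)
        rows[[length(rows) + 1L]] <- data.frame(
          landscape = res$landscape_id %||% sprintf("L%02d", li),
          treatment = treatments[ti], rep = ri, seed = s,
          t(res$summary), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired bootstrap treatment contrasts
#'
#' For each treatment, the mean percentage change of an endpoint relative to
#' the baseline treatment, pairing treatments within each landscape (the
#' experiment's grouping factor) and bootstrapping landscapes with
#' replacement for the confidence interval.
#'
#' @param table experiment table from [run_experiment()].
#' @param baseline baseline treatment (default `"garden"`).
#' @param endpoint endpoint column name.
#' @param n_boot bootstrap draws (default 1e4).
#' @param conf confidence level.
#' @return data.frame: treatment, endpoint, pct_change, lower, upper,
#'   excludes_zero.
#' @export
treatment_contrasts <- function(table, baseline = "garden", endpoint,
                                n_boot = 1e4, conf = 0.95) {
  if (!endpoint %in% names(table))
    stop(sprintf("endpoint '%s' not present in the experiment table",
                 endpoint), call. = FALSE)
  if (!baseline %in% table$treatment)
    stop("baseline treatment absent from the table", call. = FALSE)
  cell <- stats::aggregate(table[[endpoint]],
                           by = list(landscape = table$landscape,
                                     treatment = table$treatment),
                           FUN = mean)
  names(cell)[3] <- "value"
  ls_ids <- sort(unique(cell$landscape))
  base <- cell$value[match(paste(ls_ids, baseline),
                           paste(cell$landscape, cell$treatment))]
  others <- setdiff(unique(cell$treatment), baseline)
  rows <- list()
  for (tr in others) {
    val <- cell$value[match(paste(ls_ids, tr),
                            paste(cell$landscape, cell$treatment))]
    ok <- !is.na(val) & !is.na(base) & base > 0
    if (!any(ok))
      stop("baseline endpoint is zero in every landscape", call. = FALSE)
    pct <- 100 * (val[ok] - base[ok]) / base[ok]
    est <- mean(pct)
    bs <- replicate(n_boot, {
      idx <- sample(length(pct), replace = TRUE)
      mean(pct[idx])
    })
    a <- (1 - conf) / 2
    ci <- stats::quantile(bs, c(a, 1 - a), names = FALSE)
    rows[[tr]] <- data.frame(treatment = tr, endpoint = endpoint,
                             pct_change = est, lower = ci[1], upper = ci[2],
                             excludes_zero = ci[1] > 0 | ci[2] < 0,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
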
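#' Simulator configuration
#'
#' Every numeric constant of the colony simulator lives here, with defaults
#' chosen to give multi-year population persistence on intact landscapes.
#' All energies are grams of sucrose-equivalent sugar; times are minutes;
#' days are 1-based day of year.
#'
#' @param ... named overrides of the defaults listed below.
#' @return named list of class `abm_config`.
#'
#' @details Defaults:
#' \describe{
#'   \item{init_queens (500)}{hibernated queens entering year 1.}
#'   \item{years (5)}{simulated years.}
#'   \item{season (c(60, 304))}{foraging season, 1 March - 31 October.}
#'   \item{emergence_mean (91), emergence_sd (28)}{spring queen emergence,
#'     Normal(1 April, 28 d), truncated to the season (latest day 160).}
#'   \item{emergence_max (160)}{truncation of late emergence.}
#'   \item{queen_initial_energy_g (0.3)}{post-hibernation reserve.}
#'   \item{queen_maintenance_g (0.08)}{queen daily metabolic cost.}
#'   \item{founding_threshold_g (0.8)}{store a searching queen must reach to
#'     found a colony.}
#'   \item{founding_window_days (21)}{days a queen may search before dying.}
#'   \item{queen_trips (6)}{foraging trips per day by a searching queen (and
#'     by a colony before its first workers).}
#'   \item{worker_maintenance_g (0.03), brood_maintenance_g (0.01)}{daily
#'     upkeep per worker / brood item.}
#'   \item{crop_capacity_g (0.06)}{sugar carried per full crop.}
#'   \item{trips_per_forager (8)}{trips per worker per day (the daily time
#'     budget divided by a typical trip).}
#'   \item{trip_minutes_max (60)}{foraging time available within one trip.}
#'   \item{gather_rate_coef (0.02)}{g sugar gathered per minute per unit
#'     nectar density (g m-2); dilute patches fill crops slowly.}
#'   \item{corolla_scale_mm (8)}{deeper corollas slow handling by
#'     `1 + depth/scale`.}
#'   \item{flight_speed_m_min (300), flight_cost_g_min (4e-4)}{travel speed
#'     and metabolic cost of flight.}
#'   \item{detection_scale_m (500)}{patch detection decays as
#'     `exp(-distance/scale)`.}
#'   \item{brood_cost_g (0.15)}{energy to initiate one worker brood item.}
#'   \item{brood_invest_frac (0.5)}{share of the store a colony may commit
#'     to brood per day.}
#'   \item{max_eggs_per_day (10)}{queen egg-laying cap.}
#'   \item{dev_days (21)}{brood development time.}
#'   \item{max_workers (150)}{colony worker cap.}
#'   \item{starvation_days (3)}{consecutive empty-store days before death.}
#'   \item{queen_switch_day (200)}{after mid-July surplus goes to new
#'     queens.}
#'   \item{queen_cost_g (2), queen_invest_frac (0.5)}{sugar invested per new
#'     queen and daily investment share.}
#'   \item{max_queens_per_day (5)}{queen-rearing rate cap per colony (nurse
#'     capacity, not energy, limits late-season rearing).}
#'   \item{overwinter_survival (0.3)}{share of new queens surviving to next
#'     spring.}
#'   \item{carryover_cap (500)}{maximum queens carried into a year.}
#'   \item{default_corolla_mm (6)}{patch corolla depth when none is given.}
#' }
#' @export
abm_config <- function(...) {
  cfg <- list(
    init_queens = 500L, years = 5L, season = c(60L, 304L),
    emergence_mean = 91, emergence_sd = 28, emergence_max = 160L,
    queen_initial_energy_g = 0.3, queen_maintenance_g = 0.08,
    founding_threshold_g = 0.8, founding_window_days = 21L,
    queen_trips = 6, worker_maintenance_g = 0.03, brood_maintenance_g = 0.01,
    crop_capacity_g = 0.06, trips_per_forager = 8, trip_minutes_max = 60,
    gather_rate_coef = 0.02, corolla_scale_mm = 8,
    flight_speed_m_min = 300, flight_cost_g_min = 4e-4,
    detection_scale_m = 500, brood_cost_g = 0.15, brood_invest_frac = 0.5,
    max_eggs_per_day = 10, dev_days = 21L, max_workers = 150,
    starvation_days = 3L, queen_switch_day = 200L, queen_cost_g = 2,
    queen_invest_frac = 0.5, max_queens_per_day = 5,
    overwinter_survival = 0.3,
    carryover_cap = 500L, default_corolla_mm = 6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg$years <- assert_count(cfg$years, "years")
  structure(cfg, class = "abm_config")
}

#' Read or write a simulator configuration as YAML
#'
#' @param path file path.
#' @param config an [abm_config()].
#' @return `read_abm_config` returns an [abm_config()].
#' @export
write_abm_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_abm_config
#' @export
read_abm_config <- function(path) {
  do.call(abm_config, yaml::read_yaml(path))
}
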
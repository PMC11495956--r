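#' Advance the world to a day and replenish patch stocks
#'
#' Nectar stands for 24 h: each morning a patch's stock is reset to that
#' day's production (curve value times patch area), so standing stock never
#' exceeds daily production.
#'
#' @param world an `abm_world` from [build_world()].
#' @param day day of year.
#' @return the world with `day` set and `stock` replenished.
#' @export
replenish <- function(world, day) {
  stopifnot(inherits(world, "abm_world"))
  world$day <- as.integer(day)
  world$stock <- world$production[day, ]
  world
}

# indices of entities that forage today (searching queens and colonies)
.active <- function(world) which(world$entities$state >= 2L)

#' One foraging day
#'
#' Active entities (searching queens and colonies) forage in random order.
#' Each entity's trips are allocated over patches with probability
#' proportional to `exp(-distance/detection_scale) * stock`; a trip's yield
#' is capped by crop capacity, by the patch's current nectar density (dilute
#' or depleted patches fill crops slowly, deep corollas slow handling) and
#' by the stock remaining. Patch stocks fall by exactly the gross sugar
#' delivered; flight and handling time are charged as energetic costs.
#'
#' @param world an `abm_world` with entities (see [build_world()] and
#'   [init_year_entities]) and the day's stocks replenished.
#' @return the world with depleted `stock` and, per entity, the day's
#'   `gross`/`cost` in `world$last_forage`.
#' @export
daily_forage <- function(world) {
  stopifnot(inherits(world, "abm_world"))
  ent <- world$entities
  if (is.null(ent) || length(.active(world)) == 0L) {
    world$last_forage <- matrix(0, length(ent$state %||% integer(0)), 2)
    return(world)
  }
  order <- sample(.active(world))
  stock <- world$stock + 0  # private copy: the kernel mutates in place
  fg <- forage_day_cpp(stock, world$patches$area_m2, world$corolla,
                       ent$det, ent$dist, ent$state, ent$workers, order,
                       world$config)
  world$stock <- stock
  world$last_forage <- fg
  world
}

#' One colony-dynamics day
#'
#' Applies the day's net forage to every entity. Searching queens pay
#' maintenance and found a colony on reaching the founding threshold, or die
#' when their store empties or the search window closes. Colonies pay
#' maintenance, mature brood into workers, initiate brood from surplus
#' before the queen-switch date and rear new queens after it, and die after
#' `starvation_days` consecutive empty-store days. Energy stores and counts
#' never go negative; dead colonies are inert.
#'
#' @param world an `abm_world` after [daily_forage()].
#' @return the world, with the day's counters (founded, matured workers,
#'   queens produced, deaths) in `world$last_counters`.
#' @export
daily_colony_update <- function(world) {
  stopifnot(inherits(world, "abm_world"))
  ent <- world$entities
  if (is.null(ent)) return(world)
  fg <- world$last_forage %||% matrix(0, length(ent$state), 2)
  # private copies: the kernel mutates in place
  ent$state <- ent$state + 0L
  ent$energy <- ent$energy + 0
  ent$workers <- ent$workers + 0
  ent$brood <- ent$brood + 0
  ent$new_queens <- ent$new_queens + 0
  ent$starv <- ent$starv + 0L
  ent$search_days <- ent$search_days + 0L
  ctr <- colony_update_cpp(ent$state, ent$energy, ent$workers, ent$brood,
                           ent$new_queens, ent$starv, ent$search_days,
                           fg, world$day, world$config)
  world$entities <- ent
  world$last_counters <- stats::setNames(
    ctr, c("founded", "matured", "queens_produced", "died"))
  world
}
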
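## The daily schedule and multi-year simulation driver. One RNG stream
## per replicate: callers seed once, everything downstream draws from
## that stream.

#' Create a simulation state
#'
#' Bundles population, landscape, drivers and parameters into the state
#' object advanced by [step_day()]. Uses the caller's RNG stream for
#' layout and population initialisation (seed with `set.seed()` first
#' for reproducibility).
#'
#' @param scenario A [build_scenario()] result.
#' @param params A [bioenergetics_params()].
#' @param mort A [mortality_params()].
#' @param geometry A [system_geometry()].
#' @param n_init Initial post-larval population size.
#' @param landscape Optional pre-built `landscape` (built from
#'   `geometry` when `NULL`).
#' @return An object of class `sim_state`.
#' @export
init_sim_state <- function(scenario, params = bioenergetics_params(),
                           mort = mortality_params(),
                           geometry = system_geometry(), n_init = 60L,
                           landscape = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(landscape)) landscape <- init_landscape(geometry)
  pop <- init_population(n_init, landscape, params)
  structure(list(pop = pop, landscape = landscape, scenario = scenario,
                 params = params, mort = mort,
                 next_id = pop_size(pop) + 1L,
                 day_of_year = 1L, year = 1L),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: year %d day %d | %d fish | scenario %.3g degN dT %.2g\n",
              x$year, x$day_of_year, pop_size(x$pop),
              x$scenario$latitude, x$scenario$delta_t))
  invisible(x)
}

LOG_FIELDS <- c("year", "day", "n_egg", "n_larva", "n_juvenile", "n_adult",
                "biomass", "mean_mass", "mean_metabolic_rate",
                "food_renewed", "food_consumed", "food_left",
                "assimilated", "maintenance", "reproduction", "growth",
                "storage_delta", "overflow", "n_spawns", "eggs_laid")

#' Advance the simulation by one day
#'
#' Runs the daily schedule in fixed order: food renewal, ideal-free
#' movement, food sharing/ingestion/assimilation, energy allocation,
#' growth, offspring development, breeding (in season), mortality, and
#' ageing. Any failure in a sub-step is rethrown with the sub-step
#' named.
#'
#' @param state A `sim_state`.
#' @param detail If `TRUE`, attach the per-fish energy ledger and
#'   per-patch food accounting for the day (for conservation checks).
#' @return The advanced `sim_state`, with a named numeric vector `log`
#'   attached (day, year, stage counts, biomass, mean mass, mean
#'   metabolic rate, food renewed/consumed, ledger totals, eggs laid)
#'   and, if requested, `detail`.
#' @export
step_day <- function(state, detail = FALSE) {
  step <- "init"
  tryCatch({
    day <- state$day_of_year
    month <- month_of_day(day)
    temp <- state$scenario$monthly_temperature[month]
    food_density <- state$scenario$monthly_food_per_patch[month]
    params <- state$params
    pop <- state$pop

    step <- "renew_food"
    state$landscape <- renew_food(state$landscape, food_density, day)
    food_renewed <- food_density * length(state$landscape$vegetated_idx)

    step <- "move_ifd"
    pop <- move_ifd(pop, state$landscape)

    step <- "ingestion"
    feeders <- which(pop$stage >= STAGE_JUVENILE)
    intake <- numeric(pop_size(pop))
    consumed_total <- 0
    if (length(feeders)) {
      demand <- max_ingestion(pop$mass[feeders], temp, params)
      pf <- pop$patch[feeders]
      stock <- state$landscape$food[pf]
      tot_dem <- rowsum(demand, pf)
      patch_ids <- as.integer(rownames(tot_dem))
      ratio <- pmin(1, state$landscape$food[patch_ids] / pmax(tot_dem[, 1], 1e-300))
      intake[feeders] <- demand * ratio[match(pf, patch_ids)]
      eaten <- rowsum(intake[feeders], pf)
      state$landscape$food[patch_ids] <-
        state$landscape$food[patch_ids] - eaten[, 1]
      state$landscape$food[state$landscape$food < 0] <- 0
      consumed_total <- sum(eaten[, 1])
    }

    step <- "allocate_energy"
    in_season <- day >= params$breeding_season[1] &&
      day <= params$breeding_season[2]
    ledger <- NULL
    if (length(feeders)) {
      assim <- assimilate(intake[feeders], params)
      repro_active <- in_season & pop$stage[feeders] == STAGE_ADULT &
        pop$sex[feeders] == 2L
      al <- allocate_energy(pop$mass[feeders], pop$reserves[feeders],
                            pop$gonad[feeders], assim, temp, params,
                            repro_active = repro_active)
      pop$mass[feeders] <- al$mass
      pop$length[feeders] <- al$length
      pop$reserves[feeders] <- al$reserves
      pop$gonad[feeders] <- al$gonad
      pop$starved[feeders] <- al$starved
      ledger <- al
    }

    step <- "develop_offspring"
    pop <- develop_offspring(pop, temp, params)

    step <- "attempt_breeding"
    eggs_laid <- 0L
    n_spawns <- 0L
    br <- attempt_breeding(pop, state$landscape, day, params, state$next_id)
    pop <- br$pop
    eggs_laid <- br$eggs_laid
    n_spawns <- br$n_spawns
    state$next_id <- br$next_id

    step <- "apply_mortality"
    pop <- apply_mortality(pop, state$mort, state$landscape$geometry$area)

    step <- "ageing"
    pop$age <- pop$age + 1
    pop$days_since_spawn <- pop$days_since_spawn + 1
    mature <- pop$stage == STAGE_JUVENILE & pop$age >= params$maturity_age_days
    pop$stage[mature] <- STAGE_ADULT
    state$pop <- pop

    step <- "logging"
    tab <- tabulate(pop$stage, 4L)
    postlarval <- pop$stage >= STAGE_JUVENILE
    n_pl <- sum(postlarval)
    log <- c(state$year, day, tab,
             sum(pop$mass[postlarval]),
             if (n_pl > 0) sum(pop$mass[postlarval]) / n_pl else NA_real_,
             if (n_pl > 0)
               mean(maintenance_cost(pop$mass[postlarval], temp, params))
             else NA_real_,
             food_renewed, consumed_total, sum(state$landscape$food),
             if (is.null(ledger)) 0 else sum(ledger$assimilated),
             if (is.null(ledger)) 0 else sum(ledger$maintenance),
             if (is.null(ledger)) 0 else sum(ledger$reproduction),
             if (is.null(ledger)) 0 else sum(ledger$growth),
             if (is.null(ledger)) 0 else sum(ledger$storage_delta),
             if (is.null(ledger)) 0 else sum(ledger$overflow),
             n_spawns, eggs_laid)
    names(log) <- LOG_FIELDS
    state$log <- log
    if (detail) state$detail <- ledger

    state$day_of_year <- if (day >= 365L) 1L else day + 1L
    if (day >= 365L) state$year <- state$year + 1L
    state
  }, error = function(e) {
    stop(sprintf("step_day failed in sub-step `%s` (year %d, day %d): %s",
                 step, state$year, state$day_of_year, conditionMessage(e)),
         call. = FALSE)
  })
}

census_row <- function(state) {
  pop <- state$pop
  params <- state$params
  temp <- state$scenario$monthly_temperature[month_of_day(state$day_of_year)]
  postlarval <- pop$stage >= STAGE_JUVENILE
  area <- state$landscape$geometry$area
  n <- sum(postlarval)
  data.frame(year = state$year,
             abundance = n,
             density = n / area,
             biomass = sum(pop$mass[postlarval]) / area,
             mean_metabolic_rate = if (n > 0)
               mean(maintenance_cost(pop$mass[postlarval], temp, params))
             else 0)
}

#' Run a state forward over whole years with annual censuses
#'
#' Advances the state day by day for `years` years, recording a
#' pre-breeding census (default April 1) at the start of the census day
#' of each year. Census density and biomass count post-larval fish per
#' m2; mean metabolic rate is the mean individual maintenance cost at
#' the census temperature, J d-1 fish-1.
#'
#' @param state A `sim_state`.
#' @param years Number of years to simulate.
#' @param census_day Day of year of the census (default
#'   `day_of_year(4, 1)`).
#' @param daily_log Keep the per-day log rows.
#' @return A list: `state` (advanced), `census` (data.frame of one row
#'   per year), `daily` (data.frame or `NULL`), `eggs_laid` (total).
#' @export
run_years <- function(state, years, census_day = day_of_year(4, 1),
                      daily_log = FALSE) {
  census <- vector("list", years)
  daily <- if (daily_log)
    matrix(NA_real_, nrow = years * 365L, ncol = length(LOG_FIELDS),
           dimnames = list(NULL, LOG_FIELDS)) else NULL
  eggs_total <- 0
  di <- 0L
  for (y in seq_len(years)) {
    for (d in 1:365) {
      if (state$day_of_year == census_day)
        census[[y]] <- census_row(state)
      state <- step_day(state)
      eggs_total <- eggs_total + state$log[["eggs_laid"]]
      if (daily_log) { di <- di + 1L; daily[di, ] <- state$log }
    }
  }
  list(state = state,
       census = do.call(rbind, census),
       daily = if (daily_log) as.data.frame(daily) else NULL,
       eggs_laid = as.integer(eggs_total))
}

#' Simulate a population under a scenario
#'
#' Convenience driver: seeds the RNG, builds landscape and population,
#' and runs `years` years with annual pre-breeding censuses.
#'
#' @inheritParams init_sim_state
#' @param years Simulated years.
#' @param seed Integer seed for the replicate's single RNG stream.
#' @param census_day Day of year of the annual census.
#' @param daily_log Keep per-day log rows.
#' @return A list as from [run_years()].
#' @examples
#' \donttest{
#' sc <- build_scenario(55, 0)
#' out <- simulate_population(sc, years = 2, seed = 1)
#' out$census
#' }
#' @export
simulate_population <- function(scenario, years = 1L,
                                params = bioenergetics_params(),
                                mort = mortality_params(),
                                geometry = system_geometry(),
                                n_init = 60L, seed = NULL,
                                census_day = day_of_year(4, 1),
                                daily_log = FALSE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- init_sim_state(scenario, params, mort, geometry, n_init)
  run_years(state, years, census_day, daily_log)
}
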
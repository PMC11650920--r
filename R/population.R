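## The fish population: a column-oriented collection of agents and the
## daily demographic processes (movement, breeding, development,
## mortality). Stages are coded 1 = egg, 2 = larva, 3 = juvenile,
## 4 = adult; sex 1 = male, 2 = female.

STAGE_EGG <- 1L
STAGE_LARVA <- 2L
STAGE_JUVENILE <- 3L
STAGE_ADULT <- 4L

new_population <- function(n = 0L) {
  structure(list(id = integer(n), sex = integer(n), age = numeric(n),
                 stage = integer(n), mass = numeric(n),
                 reserves = numeric(n), gonad = numeric(n),
                 length = numeric(n), patch = integer(n),
                 territorial = logical(n), days_since_spawn = numeric(n),
                 develop = numeric(n), starved = logical(n)),
            class = "fish_population")
}

pop_size <- function(pop) length(pop$id)

pop_subset <- function(pop, keep) {
  for (nm in names(pop)) pop[[nm]] <- pop[[nm]][keep]
  pop
}

pop_bind <- function(pop, new) {
  for (nm in names(pop)) pop[[nm]] <- c(pop[[nm]], new[[nm]])
  pop
}

#' @export
print.fish_population <- function(x, ...) {
  tab <- tabulate(x$stage, 4L)
  cat(sprintf(
    "fish_population: %d individuals (egg %d, larva %d, juvenile %d, adult %d)\n",
    pop_size(x), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Initialise a fish population
#'
#' Creates `n` post-larval fish with stochastic age, sex and position:
#' year class drawn from a geometric distribution (most fish young of
#' the year), sex 1:1 Bernoulli, positions uniform over vegetated
#' patches. Length follows a von Bertalanffy-type age curve with 10%
#' lognormal scatter; mass from the length-weight relation; reserves
#' start at half capacity. Fish older than the maturity age are adults.
#' Uses the caller's RNG stream.
#'
#' @param n Number of fish.
#' @param landscape A `landscape` (for vegetated positions).
#' @param params A [bioenergetics_params()].
#' @param birthday Day of year the year classes are anchored to
#'   (default 182, a July 1 hatch peak); ages are measured from it to
#'   January 1, the simulation start.
#' @return A `fish_population`.
#' @export
init_population <- function(n, landscape, params = bioenergetics_params(),
                            birthday = 182L) {
  n <- as.integer(n)
  pop <- new_population(n)
  if (n == 0L) return(pop)
  year_class <- stats::rgeom(n, 0.5)
  year_class <- pmin(year_class, 2L)
  age <- (365L - as.integer(birthday)) + 365 * year_class +
    round(stats::rnorm(n, 0, 10))
  age <- pmax(age, 60)
  len <- 55 * (1 - exp(-0.004 * age)) * exp(stats::rnorm(n, 0, 0.1))
  len <- pmax(len, 15)
  mass <- mass_from_length(len, params)
  pop$id <- seq_len(n)
  pop$sex <- sample(c(1L, 2L), n, replace = TRUE)
  pop$age <- age
  pop$stage <- ifelse(age >= params$maturity_age_days, STAGE_ADULT,
                      STAGE_JUVENILE)
  pop$mass <- mass
  pop$reserves <- 0.5 * reserve_capacity(mass, params)
  pop$gonad <- numeric(n)
  pop$length <- length_from_mass(mass, params)
  pop$patch <- if (length(landscape$vegetated_idx))
    sample(landscape$vegetated_idx, n, replace = TRUE) else rep(0L, n)
  pop$days_since_spawn <- rep(params$clutch_interval, n)
  pop
}

#' Redistribute fish by the ideal free distribution
#'
#' Post-larval, non-territorial fish are reassigned across vegetated
#' patches by sequential best response in random order: each fish takes
#' the patch maximising its expected intake, patch food divided by
#' (competitors already there + 1). Territorial males hold their nest
#' patch and count as competitors. When all vegetated patches carry
#' equal food (the usual daily-reset state) the equilibrium is a
#' balanced occupancy, computed directly by randomised water-filling,
#' which yields the same occupancy profile as the sequential procedure.
#'
#' @param pop A `fish_population`.
#' @param landscape A `landscape` with the day's food stocks.
#' @return `pop` with updated `patch`.
#' @export
move_ifd <- function(pop, landscape) {
  veg <- landscape$vegetated_idx
  mobile <- which(pop$stage >= STAGE_JUVENILE & !pop$territorial)
  if (!length(mobile) || !length(veg)) return(pop)
  food <- landscape$food[veg]
  k <- length(veg)

  fixed <- which(pop$territorial)
  counts <- integer(k)
  if (length(fixed)) {
    fc <- tabulate(match(pop$patch[fixed], veg), k)
    counts <- counts + fc
  }

  m <- length(mobile)
  if (length(unique(food)) == 1L) {
    ## equal food: balanced occupancy (water-filling over current counts)
    add <- integer(k)
    total <- counts
    for (extra in seq_len(m)) {
      j <- which.min(total)
      add[j] <- add[j] + 1L
      total[j] <- total[j] + 1L
    }
    slots <- rep.int(seq_len(k), add)
    slots <- slots[sample.int(length(slots))]
    pop$patch[mobile[sample.int(m)]] <- veg[slots]
  } else {
    order_ <- mobile[sample.int(m)]
    for (i in order_) {
      j <- which.max(food / (counts + 1))
      pop$patch[i] <- veg[j]
      counts[j] <- counts[j] + 1L
    }
  }
  pop
}

#' Equilibrium ideal-free occupancies (closed form)
#'
#' Input-matching reference: `n` fish over patches with food inputs
#' `food` occupy patches proportionally to input, rounded to integers
#' by largest remainders. Used as the analytical oracle for
#' [move_ifd()].
#'
#' @param n Number of fish.
#' @param food Per-patch food inputs.
#' @return Integer occupancies summing to `n`.
#' @export
ifd_expected_occupancy <- function(n, food) {
  stopifnot(n >= 0, all(food >= 0), sum(food) > 0)
  exact <- n * food / sum(food)
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Territory competition and spawning
#'
#' During the breeding season adult males compete for nest sites: each
#' vegetated patch holds at most one territorial male, surplus males are
#' excluded that day (density-dependent reproduction). Ready females
#' (clutch interval elapsed, gonad plus spare reserves covering the
#' clutch cost) are matched to territorial males at random; a spawning
#' female lays `round(fecundity_coeff * mass)` eggs on the male's
#' patch, paying `eggs * egg_mass * tissue_energy_density` from gonad
#' first, then reserves (down to the reserve floor).
#'
#' @param pop A `fish_population`.
#' @param landscape A `landscape`.
#' @param day Day of year.
#' @param params A [bioenergetics_params()].
#' @param next_id First id for newly laid eggs.
#' @return A list: `pop` (updated adults plus new eggs), `n_spawns`,
#'   `eggs_laid`, `next_id`.
#' @export
attempt_breeding <- function(pop, landscape, day,
                             params = bioenergetics_params(),
                             next_id = max(c(0L, pop$id)) + 1L) {
  out <- list(pop = pop, n_spawns = 0L, eggs_laid = 0L, next_id = next_id)
  season <- params$breeding_season
  if (day < season[1] || day > season[2]) {
    out$pop$territorial <- rep(FALSE, pop_size(pop))
    return(out)
  }
  veg <- landscape$vegetated_idx
  if (!length(veg)) return(out)

  ## territory claims: one male per vegetated patch
  terr <- which(pop$territorial)
  taken <- pop$patch[terr]
  free <- setdiff(veg, taken)
  claimants <- which(pop$stage == STAGE_ADULT & pop$sex == 1L &
                       !pop$territorial)
  if (length(free) && length(claimants)) {
    n_claim <- min(length(free), length(claimants))
    chosen <- if (length(claimants) == 1L) claimants else
      sample(claimants, n_claim)
    sites <- if (length(free) == 1L) free else sample(free, n_claim)
    pop$territorial[chosen] <- TRUE
    pop$patch[chosen] <- sites
    terr <- which(pop$territorial)
  }
  if (!length(terr)) { out$pop <- pop; return(out) }

  ## ready females
  floor_J <- params$spawn_reserve_floor_frac *
    reserve_capacity(pop$mass, params)
  eggs_n <- round(params$fecundity_coeff * pop$mass)
  cost <- eggs_n * params$egg_mass * params$tissue_energy_density
  ready <- which(pop$stage == STAGE_ADULT & pop$sex == 2L &
                   pop$days_since_spawn >= params$clutch_interval &
                   eggs_n >= 1 &
                   pop$gonad + pmax(0, pop$reserves - floor_J) >= cost)
  if (!length(ready)) { out$pop <- pop; return(out) }

  mates <- if (length(terr) == 1L) rep(terr, length(ready)) else
    sample(terr, length(ready), replace = TRUE)

  pay_gonad <- pmin(pop$gonad[ready], cost[ready])
  pop$gonad[ready] <- pop$gonad[ready] - pay_gonad
  pop$reserves[ready] <- pop$reserves[ready] - (cost[ready] - pay_gonad)
  pop$days_since_spawn[ready] <- 0

  total_eggs <- sum(eggs_n[ready])
  eggs <- new_population(total_eggs)
  eggs$id <- seq.int(next_id, length.out = total_eggs)
  eggs$sex <- sample(c(1L, 2L), total_eggs, replace = TRUE)
  eggs$stage <- rep(STAGE_EGG, total_eggs)
  eggs$mass <- rep(params$egg_mass, total_eggs)
  eggs$patch <- rep(pop$patch[mates], eggs_n[ready])
  eggs$days_since_spawn <- rep(params$clutch_interval, total_eggs)

  list(pop = pop_bind(pop, eggs), n_spawns = length(ready),
       eggs_laid = as.integer(total_eggs),
       next_id = next_id + as.integer(total_eggs))
}

#' Temperature-dependent development of eggs and larvae
#'
#' Development accumulates daily by the (tapered) ingestion temperature
#' multiplier; an egg completes after `egg_duration_days` reference-
#' temperature days and becomes a larva, a larva after
#' `larva_duration_days` and becomes a juvenile with initial mass drawn
#' from a truncated Gaussian. No development at or below CT_min.
#'
#' @param pop A `fish_population`.
#' @param temp Temperature, deg C.
#' @param params A [bioenergetics_params()].
#' @return `pop` with stages advanced.
#' @export
develop_offspring <- function(pop, temp, params = bioenergetics_params()) {
  rate <- temperature_scaling(temp, params$q10_ingestion,
                              params$reference_temperature,
                              params$thermal_window, taper = TRUE)
  if (rate <= 0) return(pop)

  eggs <- pop$stage == STAGE_EGG
  larvae <- pop$stage == STAGE_LARVA
  pop$develop[eggs | larvae] <- pop$develop[eggs | larvae] + rate

  hatch <- eggs & pop$develop >= params$egg_duration_days - 1e-9
  if (any(hatch)) {
    pop$stage[hatch] <- STAGE_LARVA
    pop$develop[hatch] <- 0
  }
  metam <- larvae & pop$develop >= params$larva_duration_days - 1e-9
  if (any(metam)) {
    k <- sum(metam)
    m0 <- stats::rnorm(k, params$juvenile_init_mass_mean,
                       params$juvenile_init_mass_sd)
    m0 <- pmax(m0, params$juvenile_init_mass_mean / 3)
    pop$stage[metam] <- STAGE_JUVENILE
    pop$develop[metam] <- 0
    pop$mass[metam] <- m0
    pop$length[metam] <- length_from_mass(m0, params)
    pop$reserves[metam] <- 0.5 * reserve_capacity(m0, params)
  }
  pop
}

#' Daily survival
#'
#' Each fish survives with probability
#' `(1 - m_stage) / (1 + gamma * N / A)` (N = post-larval abundance,
#' A = habitat area). Starvation-flagged fish and fish beyond the
#' maximum age die deterministically.
#'
#' @param pop A `fish_population`.
#' @param mort A [mortality_params()].
#' @param area Habitat area, m2.
#' @return `pop` restricted to survivors.
#' @export
apply_mortality <- function(pop, mort = mortality_params(), area = 20) {
  n <- pop_size(pop)
  if (n == 0L) return(pop)
  n_postlarval <- sum(pop$stage >= STAGE_JUVENILE)
  penalty <- 1 / (1 + mort$gamma * n_postlarval / area)
  m_stage <- c(mort$m_egg, mort$m_larva, mort$m_juvenile,
               mort$m_adult)[pop$stage]
  p_survive <- (1 - m_stage) * penalty
  alive <- stats::runif(n) < p_survive
  alive[pop$starved] <- FALSE
  alive[pop$age > mort$max_age_days] <- FALSE
  pop_subset(pop, alive)
}
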
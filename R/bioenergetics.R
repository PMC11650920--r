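## Physiological rate functions of the fish agent. All are vectorised
## over fish (mass, reserves, ...) at a common temperature.

#' Temperature scaling of physiological rates
#'
#' Q10 multiplier `q10^((T - T_ref)/10)` inside the thermal window.
#' With `taper = TRUE` (used for ingestion, growth and development) the
#' multiplier declines linearly to zero between CT_opt and CT_max, so
#' performance saturates and collapses near the upper limit while
#' remaining continuous in T. With `taper = FALSE` (used for
#' maintenance) the pure Q10 factor applies all the way to CT_max, so
#' metabolic cost rises monotonically with warming. Outside
#' (CT_min, CT_max) the multiplier is zero.
#'
#' @param temp Temperature, deg C (vectorised).
#' @param q10 Q10 factor.
#' @param reference_temperature Reference temperature, deg C.
#' @param thermal_window `c(CT_min, CT_opt, CT_max)`.
#' @param taper Apply the linear taper above CT_opt.
#' @return Nonnegative multipliers (1 at the reference temperature when
#'   below CT_opt).
#' @examples
#' temperature_scaling(c(15, 25), 2, 15, c(0, 23, 30))
#' @export
temperature_scaling <- function(temp, q10, reference_temperature = 15,
                                thermal_window = c(0, 23, 30),
                                taper = TRUE) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  ctmin <- thermal_window[1]; ctopt <- thermal_window[2]
  ctmax <- thermal_window[3]
  s <- q10^((temp - reference_temperature) / 10)
  if (taper) {
    fade <- pmin(1, pmax(0, (ctmax - temp) / (ctmax - ctopt)))
    s <- s * fade
  }
  s[temp <= ctmin | temp >= ctmax] <- 0
  s
}

#' Maximum daily ingestion
#'
#' `max_ingestion_coeff * mass^b_ing` scaled by the (tapered) ingestion
#' temperature multiplier. Vectorised over fish.
#'
#' @param mass Structural mass, g (> 0).
#' @param temp Temperature, deg C.
#' @param params A [bioenergetics_params()].
#' @return Maximum ingestion, g food per day.
#' @export
max_ingestion <- function(mass, temp, params = bioenergetics_params()) {
  if (any(mass <= 0))
    stop("ingestion is defined for post-larval fish with positive mass",
         call. = FALSE)
  params$max_ingestion_coeff * mass^params$ingestion_mass_exponent *
    temperature_scaling(temp, params$q10_ingestion,
                        params$reference_temperature,
                        params$thermal_window, taper = TRUE)
}

#' Daily maintenance cost
#'
#' `maintenance_coeff * mass^b_met` scaled by the untapered metabolic
#' Q10 multiplier: cost rises monotonically with temperature up to
#' CT_max. Vectorised over fish.
#'
#' @inheritParams max_ingestion
#' @return Maintenance cost, J per day.
#' @export
maintenance_cost <- function(mass, temp, params = bioenergetics_params()) {
  params$maintenance_coeff * mass^params$metabolic_mass_exponent *
    temperature_scaling(temp, params$q10_metabolism,
                        params$reference_temperature,
                        params$thermal_window, taper = FALSE)
}

#' Divide limited patch food among the fish present
#'
#' If joint demand fits in the available stock everyone ingests at
#' their maximum; otherwise the stock is split in proportion to
#' individual demand (scramble competition). No intake exceeds its
#' demand and total intake never exceeds the stock.
#'
#' @param demands Per-fish demanded intake, g (>= 0).
#' @param available Food available on the patch, g (>= 0).
#' @return Per-fish intakes, g.
#' @examples
#' share_patch_food(c(0.1, 0.1), 0.1)  # half of joint demand -> 0.05 each
#' @export
share_patch_food <- function(demands, available) {
  stopifnot(all(demands >= 0), length(available) == 1L, available >= 0)
  total <- sum(demands)
  if (total <= available || total == 0) return(demands)
  demands * (available / total)
}

#' Assimilated energy from ingested food
#'
#' `ingested * food_energy_density * assimilation_efficiency`.
#'
#' @param ingested Ingested food, g (>= 0).
#' @param params A [bioenergetics_params()].
#' @return Assimilated energy, J.
#' @export
assimilate <- function(ingested, params = bioenergetics_params()) {
  stopifnot(all(ingested >= 0))
  ingested * params$food_energy_density * params$assimilation_efficiency
}

#' Reserve capacity of a fish
#'
#' @inheritParams max_ingestion
#' @return Maximum reserves, J.
#' @export
reserve_capacity <- function(mass, params = bioenergetics_params()) {
  params$max_reserve_fraction * mass * params$reserve_energy_density
}

#' Allocate a day's assimilated energy
#'
#' Implements the daily allocation cascade in priority order:
#' (1) maintenance, drawing on reserves when assimilation falls short
#' (an unpayable remainder is recorded as `deficit` and the fish is
#' flagged starved); (2) reproduction, for breeding females in season,
#' up to a daily gonad-investment quota; (3) growth, converting the
#' remaining surplus to structural mass at the tissue energy density,
#' capped by a temperature-scaled maximum growth rate; (4) storage,
#' topping up reserves to capacity with any residue discarded as
#' `overflow`.
#'
#' The ledger balances exactly:
#' `assimilated = maintenance + reproduction + growth + storage_delta +
#' overflow`, where `maintenance` is energy actually expended and
#' `storage_delta` is the realised change in reserves (negative when
#' reserves are drawn).
#'
#' @param mass Structural mass, g (vectorised over fish).
#' @param reserves Current reserves, J.
#' @param gonad Current gonad store, J.
#' @param assimilated Assimilated energy for the day, J.
#' @param temp Temperature, deg C (scalar).
#' @param params A [bioenergetics_params()].
#' @param repro_active Logical per fish: invests in gonad today
#'   (breeding-stage female in season).
#' @param growth_active Logical per fish: may grow today (post-larval).
#' @return A list of per-fish vectors: `mass`, `length`, `reserves`,
#'   `gonad`, `starved`, and the ledger columns `assimilated`,
#'   `maintenance`, `reproduction`, `growth`, `storage_delta`,
#'   `overflow`, `deficit`.
#' @export
allocate_energy <- function(mass, reserves, gonad, assimilated, temp,
                            params = bioenergetics_params(),
                            repro_active = rep(TRUE, length(mass)),
                            growth_active = rep(TRUE, length(mass))) {
  n <- length(mass)
  stopifnot(length(reserves) == n, length(gonad) == n,
            length(assimilated) == n, all(assimilated >= 0),
            all(reserves >= 0))

  maint_demand <- maintenance_cost(mass, temp, params)
  ## (1) maintenance: assimilation first, then reserves
  from_assim <- pmin(assimilated, maint_demand)
  shortfall <- maint_demand - from_assim
  from_reserves <- pmin(shortfall, reserves)
  deficit <- shortfall - from_reserves
  reserves <- reserves - from_reserves
  starved <- deficit > 1e-12
  maint_paid <- from_assim + from_reserves
  surplus <- assimilated - from_assim

  ## (2) reproduction: daily gonad quota for active breeders
  quota <- params$repro_quota_coeff * mass^params$metabolic_mass_exponent
  repro <- ifelse(repro_active, pmin(surplus, quota), 0)
  gonad <- gonad + repro
  surplus <- surplus - repro

  ## (3) growth, capped by the temperature-scaled maximum rate
  growth_cap_g <- params$max_growth_coeff *
    mass^params$ingestion_mass_exponent *
    temperature_scaling(temp, params$q10_ingestion,
                        params$reference_temperature,
                        params$thermal_window, taper = TRUE)
  mass_max <- mass_from_length(params$max_length, params)
  room <- pmax(0, mass_max - mass) * params$tissue_energy_density
  growth <- ifelse(growth_active,
                   pmin(surplus, growth_cap_g * params$tissue_energy_density,
                        room),
                   0)
  mass <- mass + growth / params$tissue_energy_density
  surplus <- surplus - growth

  ## (4) storage up to capacity; residue discarded
  cap <- reserve_capacity(mass, params)
  to_store <- pmin(surplus, pmax(0, cap - reserves))
  overflow <- surplus - to_store
  reserves <- reserves + to_store
  storage_delta <- to_store - from_reserves

  list(mass = mass,
       length = length_from_mass(mass, params),
       reserves = reserves, gonad = gonad, starved = starved,
       assimilated = assimilated, maintenance = maint_paid,
       reproduction = repro, growth = growth,
       storage_delta = storage_delta, overflow = overflow,
       deficit = deficit)
}

#' Length-weight conversions
#'
#' `mass = a * length^b` and its inverse; lengths in mm, masses in g.
#'
#' @param mass Structural mass, g.
#' @param length Standard length, mm.
#' @param params A [bioenergetics_params()].
#' @return Converted values.
#' @export
length_from_mass <- function(mass, params = bioenergetics_params()) {
  (mass / params$length_weight_a)^(1 / params$length_weight_b)
}

#' @rdname length_from_mass
#' @export
mass_from_length <- function(length, params = bioenergetics_params()) {
  params$length_weight_a * length^params$length_weight_b
}

#' Apply growth energy to a fish
#'
#' Adds `growth_energy / tissue_energy_density` to structural mass and
#' updates length by inverting the length-weight relation. Mass and
#' length never decrease.
#'
#' @param mass Structural mass, g.
#' @param growth_energy Growth energy, J (>= 0).
#' @param params A [bioenergetics_params()].
#' @return A list with updated `mass` (g) and `length` (mm).
#' @export
grow <- function(mass, growth_energy, params = bioenergetics_params()) {
  stopifnot(all(growth_energy >= 0))
  mass <- mass + growth_energy / params$tissue_energy_density
  list(mass = mass, length = length_from_mass(mass, params))
}
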
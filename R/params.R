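## Physiological and demographic parameter sets. The defaults below are
## this package's own documented choices (not fitted to any field
## dataset), selected once to give a realistic, food-limited stickleback
## population at the 20 m2 scale, and all overridable.

#' Bioenergetics parameters
#'
#' All physiological constants of the fish agent: allometric ingestion
#' and maintenance, Q10 temperature scaling with a thermal window,
#' energy densities, growth and storage limits, and the reproductive
#' schedule. Rates are per day; masses in g wet weight; energies in J;
#' lengths in mm; temperatures in deg C.
#'
#' Defaults are package conventions, not values from any field study:
#' mass exponents 0.75, Q10 = 2, reference temperature 15 deg C,
#' assimilation efficiency 0.7, breeding season May 1 -- July 31
#' (days 121--212 of the 365-day year). Override any of them, or load a
#' full profile with [read_sim_config()].
#'
#' @param max_ingestion_coeff Maximum ingestion at the reference
#'   temperature, g food per g fish^`ingestion_mass_exponent` per day.
#' @param ingestion_mass_exponent Allometric exponent of ingestion.
#' @param assimilation_efficiency Fraction of ingested energy
#'   assimilated, in (0, 1].
#' @param food_energy_density Energy content of food, J/g wet mass.
#' @param maintenance_coeff Maintenance cost at the reference
#'   temperature, J per g^`metabolic_mass_exponent` per day.
#' @param metabolic_mass_exponent Allometric exponent of maintenance.
#' @param q10_ingestion,q10_metabolism Q10 factors for ingestion and
#'   maintenance.
#' @param reference_temperature Temperature at which the rate
#'   coefficients apply, deg C.
#' @param tissue_energy_density Energy cost of structural tissue, J/g.
#' @param reserve_energy_density Energy density of reserves, J/g.
#' @param max_reserve_fraction Reserve capacity as a fraction of
#'   structural mass (reserve mass equivalent).
#' @param max_growth_coeff Maximum structural growth, g per
#'   g^`ingestion_mass_exponent` per day at the reference temperature.
#' @param max_length Asymptotic standard length, mm; structural growth
#'   stops at the corresponding mass.
#' @param length_weight_a,length_weight_b Length-weight relation
#'   `mass = a * length^b` (g, mm).
#' @param fecundity_coeff Eggs per g of female structural mass per
#'   clutch.
#' @param clutch_interval Minimum days between a female's clutches.
#' @param egg_mass Egg wet mass, g.
#' @param repro_quota_coeff Daily energy a breeding female routes to
#'   gonad when surplus allows, J per g^`metabolic_mass_exponent` per
#'   day.
#' @param spawn_reserve_floor_frac Fraction of reserve capacity a
#'   female must retain after paying for a clutch.
#' @param breeding_season `c(start, end)` days of year.
#' @param thermal_window `c(CT_min, CT_opt, CT_max)` deg C with
#'   CT_min < CT_opt < CT_max.
#' @param egg_duration_days,larva_duration_days Development durations
#'   at the reference temperature.
#' @param juvenile_init_mass_mean,juvenile_init_mass_sd Mass at the
#'   larva-to-juvenile transition, g (Gaussian, truncated positive).
#' @param maturity_age_days Age at which juveniles become adults.
#' @param carbon_to_food Carbon-to-food wet-mass conversion used by the
#'   scenario engine (default 1: carbon production taken 1:1 as food
#'   mass).
#' @return An object of class `bioenergetics_params`.
#' @examples
#' p <- bioenergetics_params(q10_metabolism = 2.2)
#' p$q10_metabolism
#' @export
bioenergetics_params <- function(max_ingestion_coeff = 0.02,
                                 ingestion_mass_exponent = 0.75,
                                 assimilation_efficiency = 0.7,
                                 food_energy_density = 20000,
                                 maintenance_coeff = 50,
                                 metabolic_mass_exponent = 0.75,
                                 q10_ingestion = 2.0,
                                 q10_metabolism = 2.0,
                                 reference_temperature = 15,
                                 tissue_energy_density = 5000,
                                 reserve_energy_density = 7000,
                                 max_reserve_fraction = 0.2,
                                 max_growth_coeff = 0.025,
                                 max_length = 60,
                                 length_weight_a = 1e-5,
                                 length_weight_b = 3,
                                 fecundity_coeff = 60,
                                 clutch_interval = 7L,
                                 egg_mass = 0.002,
                                 repro_quota_coeff = 30,
                                 spawn_reserve_floor_frac = 0.2,
                                 breeding_season = c(121L, 212L),
                                 thermal_window = c(0, 23, 30),
                                 egg_duration_days = 10,
                                 larva_duration_days = 20,
                                 juvenile_init_mass_mean = 0.01,
                                 juvenile_init_mass_sd = 0.002,
                                 maturity_age_days = 300,
                                 carbon_to_food = 1) {
  p <- list(max_ingestion_coeff = max_ingestion_coeff,
            ingestion_mass_exponent = ingestion_mass_exponent,
            assimilation_efficiency = assimilation_efficiency,
            food_energy_density = food_energy_density,
            maintenance_coeff = maintenance_coeff,
            metabolic_mass_exponent = metabolic_mass_exponent,
            q10_ingestion = q10_ingestion,
            q10_metabolism = q10_metabolism,
            reference_temperature = reference_temperature,
            tissue_energy_density = tissue_energy_density,
            reserve_energy_density = reserve_energy_density,
            max_reserve_fraction = max_reserve_fraction,
            max_growth_coeff = max_growth_coeff,
            max_length = max_length,
            length_weight_a = length_weight_a,
            length_weight_b = length_weight_b,
            fecundity_coeff = fecundity_coeff,
            clutch_interval = as.integer(clutch_interval),
            egg_mass = egg_mass,
            repro_quota_coeff = repro_quota_coeff,
            spawn_reserve_floor_frac = spawn_reserve_floor_frac,
            breeding_season = as.integer(breeding_season),
            thermal_window = thermal_window,
            egg_duration_days = egg_duration_days,
            larva_duration_days = larva_duration_days,
            juvenile_init_mass_mean = juvenile_init_mass_mean,
            juvenile_init_mass_sd = juvenile_init_mass_sd,
            maturity_age_days = maturity_age_days,
            carbon_to_food = carbon_to_food)
  validate_bioenergetics_params(p)
  structure(p, class = "bioenergetics_params")
}

validate_bioenergetics_params <- function(p) {
  pos <- c("max_ingestion_coeff", "food_energy_density", "maintenance_coeff",
           "tissue_energy_density", "reserve_energy_density",
           "max_reserve_fraction", "max_growth_coeff", "length_weight_a",
           "length_weight_b", "fecundity_coeff", "egg_mass",
           "egg_duration_days", "larva_duration_days",
           "juvenile_init_mass_mean", "maturity_age_days", "max_length",
           "q10_ingestion", "q10_metabolism", "carbon_to_food")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("`", nm, "` must be positive and finite", call. = FALSE)
  if (p$assimilation_efficiency <= 0 || p$assimilation_efficiency > 1)
    stop("`assimilation_efficiency` must be in (0, 1]", call. = FALSE)
  tw <- p$thermal_window
  if (length(tw) != 3L || !(tw[1] < tw[2] && tw[2] < tw[3]))
    stop("`thermal_window` must satisfy CT_min < CT_opt < CT_max",
         call. = FALSE)
  bs <- p$breeding_season
  if (length(bs) != 2L || bs[1] < 1L || bs[2] > 365L || bs[1] > bs[2])
    stop("`breeding_season` must be c(start, end) within 1..365",
         call. = FALSE)
  if (p$clutch_interval < 1L)
    stop("`clutch_interval` must be >= 1 day", call. = FALSE)
  invisible(p)
}

#' @export
print.bioenergetics_params <- function(x, ...) {
  cat("bioenergetics_params (package defaults unless overridden):\n")
  cat(sprintf("  ingestion %.3g g g^-%.2g d^-1, maintenance %.3g J g^-%.2g d^-1 at %g degC\n",
              x$max_ingestion_coeff, x$ingestion_mass_exponent,
              x$maintenance_coeff, x$metabolic_mass_exponent,
              x$reference_temperature))
  cat(sprintf("  Q10 ingestion %.2g / metabolism %.2g, thermal window (%g, %g, %g) degC\n",
              x$q10_ingestion, x$q10_metabolism, x$thermal_window[1],
              x$thermal_window[2], x$thermal_window[3]))
  cat(sprintf("  breeding days %d-%d, %g eggs/g per clutch every >=%d d\n",
              x$breeding_season[1], x$breeding_season[2], x$fecundity_coeff,
              x$clutch_interval))
  invisible(x)
}

#' Mortality parameters
#'
#' Stage-specific daily background mortality plus a Beverton-Holt-style
#' density penalty: each fish survives a day with probability
#' `(1 - m_stage) / (1 + gamma * N / A)` where `N` is post-larval
#' abundance and `A` the habitat area. Starved fish die
#' deterministically; fish beyond `max_age_days` die.
#'
#' @param m_egg,m_larva,m_juvenile,m_adult Daily background mortality
#'   probabilities in `[0, 1]`.
#' @param gamma Density-penalty coefficient, m2 per fish (>= 0).
#' @param max_age_days Maximum age (default 3 years).
#' @return An object of class `mortality_params`.
#' @export
mortality_params <- function(m_egg = 0.02, m_larva = 0.08,
                             m_juvenile = 0.008, m_adult = 0.004,
                             gamma = 1e-4, max_age_days = 1095) {
  p <- list(m_egg = m_egg, m_larva = m_larva, m_juvenile = m_juvenile,
            m_adult = m_adult, gamma = gamma, max_age_days = max_age_days)
  for (nm in c("m_egg", "m_larva", "m_juvenile", "m_adult"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop("`", nm, "` must be a probability", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (is.na(max_age_days) || max_age_days <= 0)
    stop("`max_age_days` must be positive (Inf disables senescence)",
         call. = FALSE)
  structure(p, class = "mortality_params")
}

#' @export
print.mortality_params <- function(x, ...) {
  cat(sprintf(
    "mortality_params: daily m egg %.3g, larva %.3g, juvenile %.3g, adult %.3g; gamma %.3g m2/fish; max age %g d\n",
    x$m_egg, x$m_larva, x$m_juvenile, x$m_adult, x$gamma, x$max_age_days))
  invisible(x)
}
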
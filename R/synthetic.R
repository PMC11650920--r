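## Synthetic driver generators: seasonal temperature curves, GPP-latitude
## datasets, and ration-experiment fixtures. All are pure functions of
## (spec, seed).

#' Seasonal temperature template
#'
#' Describes a sinusoidal annual water-temperature cycle:
#' `annual_mean + amplitude * cos(2*pi*(m - phase_month)/12)` plus
#' optional Gaussian noise.
#'
#' @param annual_mean Annual mean temperature, deg C.
#' @param amplitude Seasonal half-range, deg C (>= 0).
#' @param phase_month Warmest month, 1--12 (default 7, July).
#' @param noise_sd SD of month-to-month Gaussian noise, deg C (>= 0).
#' @return An object of class `seasonal_template`.
#' @export
seasonal_template <- function(annual_mean, amplitude = 7, phase_month = 7L,
                              noise_sd = 0) {
  stopifnot(is.finite(annual_mean), is.finite(amplitude), amplitude >= 0,
            phase_month %in% 1:12, is.finite(noise_sd), noise_sd >= 0)
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 phase_month = as.integer(phase_month), noise_sd = noise_sd),
            class = "seasonal_template")
}

#' Generate 12 monthly temperatures from a template
#'
#' @param template A [seasonal_template()].
#' @param seed Optional integer seed (required when `noise_sd > 0` for
#'   reproducibility).
#' @return Numeric vector of 12 monthly temperatures, deg C.
#' @examples
#' make_monthly_temperatures(seasonal_template(10, 7))
#' @export
make_monthly_temperatures <- function(template, seed = NULL) {
  stopifnot(inherits(template, "seasonal_template"))
  m <- 1:12
  temps <- template$annual_mean +
    template$amplitude * cos(2 * pi * (m - template$phase_month) / 12)
  if (template$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    temps <- temps + stats::rnorm(12, 0, template$noise_sd)
  }
  temps
}

#' Default baseline monthly water temperatures for a latitude
#'
#' Repo-convention seasonal baselines for the 50--60 degrees N study
#' band (not taken from any field dataset): annual means decline
#' linearly from 11 deg C at 50 degrees N to 8 deg C at 60 degrees N,
#' with a 7 deg C amplitude and a July peak. Users with measured monthly
#' tables should supply them instead.
#'
#' @param lat Latitude, degrees N.
#' @return Numeric vector of 12 monthly temperatures, deg C.
#' @export
default_monthly_temperatures <- function(lat) {
  stopifnot(is.finite(lat))
  annual_mean <- 11 - 0.3 * (lat - 50)
  make_monthly_temperatures(seasonal_template(annual_mean, amplitude = 7,
                                              phase_month = 7L, noise_sd = 0))
}

#' Default within-year food shape
#'
#' Repo-convention seasonal pattern of food production (relative
#' weights; the scenario engine rescales them to the latitude's annual
#' mean): a summer-peaking sinusoid, July maximum, winter minimum at
#' 40% of peak.
#'
#' @return Numeric vector of 12 positive weights.
#' @export
default_food_shape <- function() {
  m <- 1:12
  1 + 0.43 * cos(2 * pi * (m - 7) / 12)
}

#' GPP-latitude dataset specification
#'
#' Describes a synthetic compilation of river gross primary production
#' observations across latitudes with a linear trend plus Gaussian
#' noise, emulating a multi-study global dataset.
#'
#' @param n_sites Number of sites (>= 3).
#' @param latitude_range `c(lo, hi)` in degrees N (default 18--78).
#' @param true_slope,true_intercept Trend coefficients,
#'   mg C m-2 d-1 per degree N and mg C m-2 d-1.
#' @param noise_sd Residual SD, mg C m-2 d-1; default chosen with
#'   [noise_sd_for_r2()] to give R2 of about 0.16 over the latitude
#'   range, matching the dispersion of the global compilation the trend
#'   comes from.
#' @param seed Integer seed.
#' @return An object of class `gpp_dataset_spec`.
#' @export
gpp_dataset_spec <- function(n_sites = 27L, latitude_range = c(18, 78),
                             true_slope = 38.13, true_intercept = 88.0,
                             noise_sd = noise_sd_for_r2(true_slope,
                                                        latitude_range, 0.16),
                             seed = 1L) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 3L, length(latitude_range) == 2L,
            latitude_range[1] < latitude_range[2],
            is.finite(true_slope), is.finite(true_intercept),
            is.finite(noise_sd), noise_sd >= 0)
  structure(list(n_sites = n_sites, latitude_range = latitude_range,
                 true_slope = true_slope, true_intercept = true_intercept,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "gpp_dataset_spec")
}

#' Residual SD that yields a target regression R2
#'
#' For predictors uniform on `range`, solves
#' `R2 = s^2 var(x) / (s^2 var(x) + sigma^2)` for `sigma`.
#'
#' @param slope True slope.
#' @param range Predictor range `c(lo, hi)` (uniform).
#' @param r2 Target R2 in (0, 1).
#' @return Residual SD.
#' @export
noise_sd_for_r2 <- function(slope, range, r2) {
  stopifnot(r2 > 0, r2 < 1)
  var_x <- diff(range)^2 / 12
  sqrt(slope^2 * var_x * (1 - r2) / r2)
}

#' Generate a synthetic (latitude, GPP) dataset
#'
#' Latitudes are uniform on the spec's range; GPP is the linear trend
#' plus Gaussian noise. Deterministic under the spec's seed.
#'
#' @param spec A [gpp_dataset_spec()].
#' @return Data frame with columns `latitude` and `gpp`.
#' @examples
#' d <- make_gpp_dataset(gpp_dataset_spec(n_sites = 27, seed = 42))
#' coef(lm(gpp ~ latitude, d))
#' @export
make_gpp_dataset <- function(spec) {
  stopifnot(inherits(spec, "gpp_dataset_spec"))
  set.seed(spec$seed)
  lat <- stats::runif(spec$n_sites, spec$latitude_range[1],
                      spec$latitude_range[2])
  gpp <- spec$true_slope * lat + spec$true_intercept +
    stats::rnorm(spec$n_sites, 0, spec$noise_sd)
  data.frame(latitude = lat, gpp = gpp)
}

#' Read a (latitude, GPP) dataset from delimited text
#'
#' Comma-separated, header row, two numeric columns named `latitude`
#' and `gpp` (extra columns are ignored).
#'
#' @param path File path.
#' @return Data frame with columns `latitude` and `gpp`.
#' @export
read_gpp_dataset <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("latitude", "gpp") %in% names(x)))
    stop("dataset must have columns `latitude` and `gpp`", call. = FALSE)
  if (!is.numeric(x$latitude) || !is.numeric(x$gpp))
    stop("`latitude` and `gpp` must be numeric", call. = FALSE)
  x[, c("latitude", "gpp")]
}

#' Single-fish ration-experiment configurations
#'
#' Emits competition-free, constant-temperature simulation
#' configurations that differ only in food density, one per ration
#' level, for growth/fecundity monotonicity checks (low vs medium vs
#' high rations).
#'
#' @param levels Increasing food densities, g patch-1 d-1 (>= 1 level).
#' @param years Simulated years per configuration.
#' @param temperature Constant water temperature, deg C.
#' @param seed Base seed; level `i` gets `seed + i - 1`.
#' @return A list of configuration lists with elements `food_density`,
#'   `temperature`, `years` and `seed`, in ascending ration order.
#' @export
make_ration_fixture <- function(levels, years = 1L, temperature = 15,
                                seed = 1L) {
  stopifnot(is.numeric(levels), length(levels) >= 1L, all(levels > 0),
            !is.unsorted(levels, strictly = TRUE))
  lapply(seq_along(levels), function(i) {
    list(food_density = levels[i], temperature = temperature,
         years = as.integer(years), seed = as.integer(seed) + i - 1L)
  })
}

#' Run a competition-free ration experiment
#'
#' Simulates one adult pair (a male and a female, both starting at
#' `init_mass`) per ration level under constant temperature and food,
#' with background mortality off and eggs removed at laying, so growth
#' and egg production reflect the ration alone. The validation-style
#' check this supports: final female length, mass and egg production
#' should increase from low to medium to high rations.
#'
#' @param fixture Configuration list from [make_ration_fixture()].
#' @param params A [bioenergetics_params()].
#' @param geometry A [system_geometry()].
#' @return Data frame: `food_density`, `final_length`, `final_mass`
#'   (the female's), `eggs_laid` (total over the run).
#' @export
run_ration_experiment <- function(fixture, params = bioenergetics_params(),
                                  geometry = system_geometry()) {
  mort <- mortality_params(m_egg = 1, m_larva = 0, m_juvenile = 0,
                           m_adult = 0, gamma = 0, max_age_days = Inf)
  rows <- lapply(fixture, function(cf) {
    set.seed(cf$seed)
    scen <- constant_scenario(cf$food_density, cf$temperature)
    landscape <- init_landscape(geometry)
    pop <- new_population(2L)
    pop$id <- 1:2
    pop$sex <- c(1L, 2L)
    pop$age <- c(365, 365)
    pop$stage <- rep(STAGE_ADULT, 2L)
    pop$mass <- rep(0.15, 2L)
    pop$length <- length_from_mass(pop$mass, params)
    pop$reserves <- 0.5 * reserve_capacity(pop$mass, params)
    pop$patch <- landscape$vegetated_idx[1:2]
    pop$days_since_spawn <- rep(params$clutch_interval, 2L)
    state <- structure(list(pop = pop, landscape = landscape,
                            scenario = scen, params = params, mort = mort,
                            next_id = 3L, day_of_year = 1L, year = 1L),
                       class = "sim_state")
    out <- run_years(state, cf$years)
    female <- which(out$state$pop$sex == 2L)
    data.frame(food_density = cf$food_density,
               final_length = out$state$pop$length[female],
               final_mass = out$state$pop$mass[female],
               eggs_laid = out$eggs_laid)
  })
  do.call(rbind, rows)
}
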
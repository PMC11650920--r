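## Scenario engine: latitude + IPCC warming level -> monthly temperature
## and per-patch food schedules, built from three published environmental
## regressions.

#' Linear regression specification
#'
#' Container for the slope/intercept of an environmental regression,
#' with the scale on which the response is modelled.
#'
#' @param slope,intercept Regression coefficients (finite reals).
#' @param response_scale `"linear"` or `"log10"`; determines whether
#'   predictions need back-transformation.
#' @return An object of class `regression_spec`.
#' @seealso [gpp_latitude_regression()], [pcp_gpp_regression()],
#'   [macroinvertebrate_temperature_regression()]
#' @export
regression_spec <- function(slope, intercept,
                            response_scale = c("linear", "log10")) {
  response_scale <- match.arg(response_scale)
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  structure(list(slope = slope, intercept = intercept,
                 response_scale = response_scale),
            class = "regression_spec")
}

#' @export
print.regression_spec <- function(x, ...) {
  cat(sprintf("regression_spec: y%s = %g * x + %g\n",
              if (x$response_scale == "log10") " (log10)" else "",
              x$slope, x$intercept))
  invisible(x)
}

#' Published environmental regressions
#'
#' The three regressions the scenario engine is built on:
#' river gross primary production (GPP, mg C m-2 d-1) as a linear
#' function of latitude (degrees N); daily primary consumer (secondary)
#' production (mg C m-2 d-1) as a linear function of GPP; and
#' macroinvertebrate community biomass (log10 mg m-2) as a linear
#' function of water temperature (deg C).
#'
#' @return A [regression_spec()].
#' @examples
#' predict_regression(gpp_latitude_regression(), 55)
#' @export
gpp_latitude_regression <- function() regression_spec(38.13, 88.0, "linear")

#' @rdname gpp_latitude_regression
#' @export
pcp_gpp_regression <- function() regression_spec(0.02, 9.04, "linear")

#' @rdname gpp_latitude_regression
#' @export
macroinvertebrate_temperature_regression <- function()
  regression_spec(0.138, 1.090, "log10")

#' Predict from a regression specification
#'
#' @param spec A [regression_spec()].
#' @param x Predictor values.
#' @param back_transform If `TRUE` and the response scale is log10,
#'   return `10^prediction`.
#' @return Predicted response values.
#' @export
predict_regression <- function(spec, x, back_transform = FALSE) {
  stopifnot(inherits(spec, "regression_spec"), is.numeric(x))
  y <- spec$slope * x + spec$intercept
  if (back_transform && spec$response_scale == "log10") 10^y else y
}

#' Gross primary production from latitude
#'
#' River GPP (mg C m-2 d-1) as a linear function of latitude (degrees N),
#' GPP = 38.13 * lat + 88.0. The relation was established for rivers
#' between 18 and 78 degrees N; latitudes outside that range trigger a
#' warning but are still evaluated.
#'
#' @param lat Latitude in degrees N (finite numeric, vectorised).
#' @return GPP in mg C m-2 d-1.
#' @examples
#' gpp_from_latitude(c(50, 55, 60))
#' @export
gpp_from_latitude <- function(lat) {
  if (!is.numeric(lat) || any(!is.finite(lat)))
    stop("`lat` must be finite numeric", call. = FALSE)
  if (any(lat < 18 | lat > 78))
    warning("latitude outside the verified 18-78 degrees N range", call. = FALSE)
  predict_regression(gpp_latitude_regression(), lat)
}

#' Primary consumer production from gross primary production
#'
#' Daily primary consumer (secondary) production, mg C m-2 d-1, as a
#' linear function of GPP: PCP = 0.02 * GPP + 9.04.
#'
#' @param gpp GPP in mg C m-2 d-1 (nonnegative, vectorised).
#' @return Primary consumer production in mg C m-2 d-1.
#' @examples
#' pcp_from_gpp(gpp_from_latitude(50))
#' @export
pcp_from_gpp <- function(gpp) {
  if (!is.numeric(gpp) || any(!is.finite(gpp)) || any(gpp < 0))
    stop("`gpp` must be finite and nonnegative", call. = FALSE)
  predict_regression(pcp_gpp_regression(), gpp)
}

#' Convert areal production to food mass per vegetated patch
#'
#' Spreads daily primary consumer production over the habitat area and
#' divides it among the vegetated (food-bearing) patches only:
#' `pcp * area / 1000 / n_vegetated` (mg -> g). Carbon production is
#' taken 1:1 as available food wet mass; `carbon_to_food` rescales that
#' assumption if desired.
#'
#' @param pcp Primary consumer production, mg C m-2 d-1 (nonnegative).
#' @param geometry A [system_geometry()].
#' @param carbon_to_food Multiplier converting carbon production to food
#'   mass (default 1).
#' @return Food in g per vegetated patch per day.
#' @examples
#' # the three annual food densities at 50/55/60 degrees N
#' round(food_per_patch(pcp_from_gpp(gpp_from_latitude(c(50, 55, 60)))), 4)
#' @export
food_per_patch <- function(pcp, geometry = system_geometry(),
                           carbon_to_food = 1) {
  if (!is.numeric(pcp) || any(!is.finite(pcp)) || any(pcp < 0))
    stop("`pcp` must be finite and nonnegative", call. = FALSE)
  stopifnot(inherits(geometry, "system_geometry"))
  if (geometry$n_vegetated == 0L)
    stop("geometry has zero vegetated patches; food per patch undefined",
         call. = FALSE)
  pcp * carbon_to_food * geometry$area / 1000 / geometry$n_vegetated
}

#' Warming offset on log10 macroinvertebrate biomass
#'
#' The additive offset on log10 macroinvertebrate biomass (mg m-2)
#' implied by a temperature rise: `1.090 + 0.138 * delta_t`. At the
#' IPCC 2100 warming levels 1.4 / 2.7 / 4.4 deg C this evaluates to
#' 1.28 / 1.46 / 1.70 (2 dp).
#'
#' @param delta_t Temperature rise in deg C (nonnegative, vectorised).
#' @return Offset in log10 mg m-2 (unrounded; round to 2 dp for
#'   scenario labelling).
#' @examples
#' round(warming_log10_offset(c(1.4, 2.7, 4.4)), 2)
#' @export
warming_log10_offset <- function(delta_t) {
  if (!is.numeric(delta_t) || any(!is.finite(delta_t)) || any(delta_t < 0))
    stop("`delta_t` must be finite and nonnegative", call. = FALSE)
  reg <- macroinvertebrate_temperature_regression()
  reg$intercept + reg$slope * delta_t
}

#' Multiplicative food increase under warming
#'
#' The net factor by which food density increases for a temperature
#' rise `delta_t`: `10^(0.138 * delta_t)`. Adding the warming offset to
#' log10 food, removing the baseline intercept and back-transforming is
#' equivalent to multiplying by this factor.
#'
#' @inheritParams warming_log10_offset
#' @return Dimensionless multiplier (1 at `delta_t = 0`).
#' @export
warming_food_factor <- function(delta_t) {
  reg <- macroinvertebrate_temperature_regression()
  10^(warming_log10_offset(delta_t) - reg$intercept)
}

#' Apply the warming-driven food increase to a baseline food density
#'
#' @param baseline_food Baseline food density, g patch-1 d-1 (positive).
#' @inheritParams warming_log10_offset
#' @return Warming-adjusted food density, g patch-1 d-1.
#' @examples
#' apply_warming_food_increase(0.0196, 1.4)
#' @export
apply_warming_food_increase <- function(baseline_food, delta_t) {
  if (!is.numeric(baseline_food) || any(!is.finite(baseline_food)) ||
      any(baseline_food <= 0))
    stop("`baseline_food` must be finite and positive", call. = FALSE)
  baseline_food * warming_food_factor(delta_t)
}

#' Annual mean food density for a latitude and warming level
#'
#' Chains the regressions: latitude -> GPP -> primary consumer
#' production -> g per vegetated patch per day, then applies the
#' warming food factor.
#'
#' @param lat Latitude, degrees N.
#' @param delta_t Temperature rise, deg C.
#' @param geometry A [system_geometry()].
#' @param carbon_to_food Carbon-to-food-mass multiplier (default 1).
#' @return Annual mean food density, g patch-1 d-1.
#' @export
annual_food_density <- function(lat, delta_t = 0,
                                geometry = system_geometry(),
                                carbon_to_food = 1) {
  base <- food_per_patch(pcp_from_gpp(gpp_from_latitude(lat)), geometry,
                         carbon_to_food)
  base * warming_food_factor(delta_t)
}

#' Build a latitude x warming scenario
#'
#' Resolves a latitude and a temperature-rise level into 12-month
#' temperature and per-patch food schedules. Monthly food follows the
#' supplied seasonal shape, rescaled so its mean equals the
#' (warming-adjusted) annual mean food density for the latitude; the
#' shape is scale-invariant. Monthly temperature is the baseline series
#' plus `delta_t` elementwise.
#'
#' @param lat Latitude, degrees N (the study spans 50--60).
#' @param delta_t Temperature rise, deg C; the IPCC 2100 levels are
#'   0 / 1.4 / 2.7 / 4.4.
#' @param seasonal_shape 12 positive weights giving the within-year food
#'   pattern; only their relative sizes matter. Default
#'   [default_food_shape()].
#' @param monthly_temperature_baseline 12 baseline monthly water
#'   temperatures, deg C. Default [default_monthly_temperatures()] for
#'   the latitude.
#' @param geometry A [system_geometry()].
#' @param carbon_to_food Carbon-to-food-mass multiplier (default 1).
#' @return An object of class `scenario`: a list with `latitude`,
#'   `delta_t`, `monthly_temperature` (12, deg C),
#'   `monthly_food_per_patch` (12, g patch-1 d-1) and
#'   `annual_mean_food` (g patch-1 d-1).
#' @examples
#' sc <- build_scenario(55, 2.7)
#' sc$annual_mean_food
#' @export
build_scenario <- function(lat, delta_t = 0,
                           seasonal_shape = default_food_shape(),
                           monthly_temperature_baseline =
                             default_monthly_temperatures(lat),
                           geometry = system_geometry(),
                           carbon_to_food = 1) {
  stopifnot(length(lat) == 1L, length(delta_t) == 1L)
  if (!is.numeric(seasonal_shape) || length(seasonal_shape) != 12L ||
      any(!is.finite(seasonal_shape)) || any(seasonal_shape <= 0))
    stop("`seasonal_shape` must be 12 positive weights", call. = FALSE)
  if (!is.numeric(monthly_temperature_baseline) ||
      length(monthly_temperature_baseline) != 12L ||
      any(!is.finite(monthly_temperature_baseline)))
    stop("`monthly_temperature_baseline` must be 12 finite temperatures",
         call. = FALSE)
  mean_food <- annual_food_density(lat, delta_t, geometry, carbon_to_food)
  food <- seasonal_shape / mean(seasonal_shape) * mean_food
  structure(list(latitude = lat, delta_t = delta_t,
                 monthly_temperature = monthly_temperature_baseline + delta_t,
                 monthly_food_per_patch = food,
                 annual_mean_food = mean_food),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: %.4g degN, dT = %.2g degC | annual mean food %.4f g/patch/d\n",
    x$latitude, x$delta_t, x$annual_mean_food))
  cat("  temp (degC):", paste(sprintf("%.1f", x$monthly_temperature),
                              collapse = " "), "\n")
  cat("  food (g)   :", paste(sprintf("%.4f", x$monthly_food_per_patch),
                              collapse = " "), "\n")
  invisible(x)
}

#' Constant-driver scenario
#'
#' A degenerate scenario with the same temperature and per-patch food
#' density in every month — the setting of controlled ration
#' experiments.
#'
#' @param food_density Food per vegetated patch, g patch-1 d-1 (>= 0).
#' @param temperature Water temperature, deg C.
#' @return A `scenario` with `latitude = NA`.
#' @export
constant_scenario <- function(food_density, temperature = 15) {
  stopifnot(is.finite(food_density), food_density >= 0,
            is.finite(temperature))
  structure(list(latitude = NA_real_, delta_t = 0,
                 monthly_temperature = rep(temperature, 12L),
                 monthly_food_per_patch = rep(food_density, 12L),
                 annual_mean_food = food_density),
            class = "scenario")
}

#' Read or write a monthly driver table
#'
#' Delimited-text interface for 12-row monthly driver tables with
#' columns `month` (1--12), `temperature_c` and `food_g_patch_day`.
#'
#' @param path File path (comma-separated, header row).
#' @param scenario A `scenario` object (for writing).
#' @return `read_monthly_drivers()` returns a data.frame with the three
#'   columns in month order; `write_monthly_drivers()` invisibly returns
#'   `path`.
#' @export
read_monthly_drivers <- function(path) {
  x <- utils::read.csv(path)
  need <- c("month", "temperature_c", "food_g_patch_day")
  if (!all(need %in% names(x)))
    stop("driver table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- x[order(x$month), need]
  if (!identical(as.integer(x$month), 1:12))
    stop("driver table must contain months 1..12 exactly once", call. = FALSE)
  if (any(x$food_g_patch_day < 0)) stop("food must be nonnegative", call. = FALSE)
  x
}

#' @rdname read_monthly_drivers
#' @export
write_monthly_drivers <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  utils::write.csv(data.frame(month = 1:12,
                              temperature_c = scenario$monthly_temperature,
                              food_g_patch_day = scenario$monthly_food_per_patch),
                   path, row.names = FALSE)
  invisible(path)
}

#' Build a scenario from a monthly driver table
#'
#' Uses the table's temperatures as the baseline series and its food
#' column (rescaled to the latitude's annual mean) as the seasonal shape.
#'
#' @param drivers Data frame from [read_monthly_drivers()].
#' @inheritParams build_scenario
#' @return A `scenario`.
#' @export
scenario_from_drivers <- function(drivers, lat, delta_t = 0,
                                  geometry = system_geometry()) {
  shape <- drivers$food_g_patch_day
  if (any(shape <= 0))
    stop("driver food values must be positive to define a seasonal shape",
         call. = FALSE)
  build_scenario(lat, delta_t, seasonal_shape = shape,
                 monthly_temperature_baseline = drivers$temperature_c,
                 geometry = geometry)
}
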
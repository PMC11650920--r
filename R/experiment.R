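## The simulation experiment: warm-up under present-day drivers, switch
## to a warming scenario, replication, annual pre-breeding census, and
## effect detection against the unwarmed control.

#' Experiment configuration
#'
#' The full factorial design: latitudes x temperature-rise levels x
#' replicates, each run as warm-up years under present-day (dT = 0)
#' drivers followed by treatment years under the scenario drivers, with
#' an annual pre-breeding census (default April 1). The study design
#' uses a 10-year warm-up, 10 treatment years and 15 replicates;
#' defaults here are that design, scalable down for quick runs.
#'
#' @param latitudes Latitudes, degrees N.
#' @param delta_ts Temperature-rise levels, deg C; must include 0 (the
#'   control).
#' @param warmup_years,treatment_years Years before/after the scenario
#'   switch.
#' @param n_replicates Replicates per latitude x dT cell.
#' @param census_month_day `c(month, day)` of the census.
#' @param base_seed Base integer seed; replicate r at latitude index i
#'   uses the stream seeded with `base_seed + 1000 * i + r`, shared
#'   across dT levels so treatments are paired with their control.
#' @param detection_threshold Relative deviation from control counted
#'   as a detectable population-level effect (default 0.05).
#' @param n_init Initial population size per run.
#' @param params,mort,geometry Model parameter objects.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(latitudes = c(50, 55, 60),
                              delta_ts = c(0, 1.4, 2.7, 4.4),
                              warmup_years = 10L, treatment_years = 10L,
                              n_replicates = 15L,
                              census_month_day = c(4L, 1L),
                              base_seed = 1L,
                              detection_threshold = 0.05,
                              n_init = 60L,
                              params = bioenergetics_params(),
                              mort = mortality_params(),
                              geometry = system_geometry()) {
  stopifnot(length(latitudes) >= 1L, n_replicates >= 1L,
            warmup_years >= 0L, treatment_years >= 1L,
            detection_threshold > 0)
  if (!any(delta_ts == 0))
    stop("`delta_ts` must include 0 (the control scenario)", call. = FALSE)
  structure(list(latitudes = latitudes, delta_ts = delta_ts,
                 warmup_years = as.integer(warmup_years),
                 treatment_years = as.integer(treatment_years),
                 n_replicates = as.integer(n_replicates),
                 census_month_day = as.integer(census_month_day),
                 base_seed = as.integer(base_seed),
                 detection_threshold = detection_threshold,
                 n_init = as.integer(n_init),
                 params = params, mort = mort, geometry = geometry),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "experiment_config: %d latitudes x %d dT levels x %d replicates, %d+%d years, seed %d\n",
    length(x$latitudes), length(x$delta_ts), x$n_replicates,
    x$warmup_years, x$treatment_years, x$base_seed))
  invisible(x)
}

#' Run the full simulation experiment
#'
#' For every latitude and replicate, a warm-up population is simulated
#' under the present-day scenario; its state is then continued under
#' each temperature-rise level (including the dT = 0 control) for the
#' treatment years, recording a pre-breeding census each year. Sharing
#' the warm-up within a replicate pairs each treatment with its
#' control; each continuation runs on its own deterministic RNG
#' stream, so results are independent of the order in which cells are
#' executed.
#'
#' Extinct replicates are retained as zero-density census rows (and
#' flagged), not dropped.
#'
#' @param config An [experiment_config()].
#' @param progress Print a line per latitude x replicate.
#' @return A data.frame of census records: `latitude`, `delta_t`,
#'   `replicate`, `year` (1-based treatment year), `abundance`,
#'   `density` (fish m-2), `biomass` (g m-2), `mean_metabolic_rate`
#'   (J d-1 fish-1) and `extinct`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  census_day <- day_of_year(config$census_month_day[1],
                            config$census_month_day[2])
  rows <- list()
  k <- 0L
  for (i in seq_along(config$latitudes)) {
    lat <- config$latitudes[i]
    scen0 <- build_scenario(lat, 0, geometry = config$geometry,
                            carbon_to_food = config$params$carbon_to_food)
    scens <- lapply(config$delta_ts, function(dt)
      build_scenario(lat, dt, geometry = config$geometry,
                     carbon_to_food = config$params$carbon_to_food))
    for (r in seq_len(config$n_replicates)) {
      seed_r <- config$base_seed + 1000L * i + r
      set.seed(seed_r)
      state0 <- init_sim_state(scen0, config$params, config$mort,
                               config$geometry, config$n_init)
      if (config$warmup_years > 0L)
        state0 <- run_years(state0, config$warmup_years, census_day)$state
      for (j in seq_along(config$delta_ts)) {
        state <- state0
        state$scenario <- scens[[j]]
        ## common random numbers across dT levels within a replicate:
        ## every continuation restarts the same stream, so treatment vs
        ## control differences reflect the drivers, not the draws
        set.seed(seed_r + 99991L)
        out <- run_years(state, config$treatment_years, census_day)
        cen <- out$census
        k <- k + 1L
        rows[[k]] <- data.frame(latitude = lat,
                                delta_t = config$delta_ts[j],
                                replicate = r,
                                year = seq_len(nrow(cen)),
                                abundance = cen$abundance,
                                density = cen$density,
                                biomass = cen$biomass,
                                mean_metabolic_rate = cen$mean_metabolic_rate,
                                extinct = cen$abundance == 0L)
      }
      if (progress)
        message(sprintf("latitude %g, replicate %d done", lat, r))
    }
  }
  do.call(rbind, rows)
}

#' Percent change of a treatment mean against its control
#'
#' `100 * (treatment - control) / control`, signed.
#'
#' @param control_mean Control mean (> 0).
#' @param treatment_mean Treatment mean.
#' @return Percent change.
#' @examples
#' percent_change(10, 20.8)  # +108
#' @export
percent_change <- function(control_mean, treatment_mean) {
  if (any(control_mean <= 0))
    stop("percent change is undefined for a nonpositive control mean",
         call. = FALSE)
  100 * (treatment_mean - control_mean) / control_mean
}

#' Detect a population-level effect against the control
#'
#' A treatment effect on an endpoint is considered detectable when the
#' mean over the treatment decade (annual censuses averaged within
#' replicate, then over replicates) deviates from the control mean by
#' more than the detection threshold (default 5%). The final-year
#' percent change is reported alongside.
#'
#' @param control_records,treatment_records Census data.frames from
#'   [run_experiment()] restricted to one latitude and one dT level
#'   each (control must be dT = 0 at the same latitude).
#' @param endpoint `"density"` or `"biomass"`.
#' @param threshold Detection threshold (fraction).
#' @return A one-row data.frame: `latitude`, `delta_t`, `endpoint`,
#'   `percent_change` (10-year means), `final_year_percent_change`,
#'   `detectable`.
#' @export
detect_effect <- function(control_records, treatment_records,
                          endpoint = c("density", "biomass"),
                          threshold = 0.05) {
  endpoint <- match.arg(endpoint)
  if (!nrow(control_records) || !nrow(treatment_records))
    stop("both census groups must be non-empty", call. = FALSE)
  if (length(unique(control_records$latitude)) != 1L ||
      length(unique(treatment_records$latitude)) != 1L ||
      control_records$latitude[1] != treatment_records$latitude[1])
    stop("control and treatment must come from the same latitude",
         call. = FALSE)
  ctrl <- mean(tapply(control_records[[endpoint]],
                      control_records$replicate, mean))
  trt <- mean(tapply(treatment_records[[endpoint]],
                     treatment_records$replicate, mean))
  pc <- percent_change(ctrl, trt)
  ymax_c <- max(control_records$year)
  ymax_t <- max(treatment_records$year)
  fc <- mean(control_records[[endpoint]][control_records$year == ymax_c])
  ft <- mean(treatment_records[[endpoint]][treatment_records$year == ymax_t])
  data.frame(latitude = control_records$latitude[1],
             delta_t = treatment_records$delta_t[1],
             endpoint = endpoint,
             percent_change = pc,
             final_year_percent_change = percent_change(fc, ft),
             detectable = abs(pc) / 100 > threshold)
}

#' Summarise the final pre-breeding census
#'
#' Per latitude x dT cell: replicate mean and SD of density, biomass
#' and mean metabolic rate in the final treatment year, with percent
#' change against the dT = 0 control of the same latitude (omitted
#' with a warning when no control rows are present).
#'
#' @param census Census data.frame from [run_experiment()].
#' @return A data.frame with one row per latitude x dT cell.
#' @export
summarize_final_census <- function(census) {
  ymax <- max(census$year)
  fin <- census[census$year == ymax, ]
  cells <- unique(fin[, c("latitude", "delta_t")])
  cells <- cells[order(cells$latitude, cells$delta_t), ]
  has_control <- any(fin$delta_t == 0)
  if (!has_control)
    warning("no dT = 0 control rows: percent-change columns omitted",
            call. = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    lat <- cells$latitude[i]; dt <- cells$delta_t[i]
    g <- fin[fin$latitude == lat & fin$delta_t == dt, ]
    row <- data.frame(latitude = lat, delta_t = dt,
                      n_replicates = nrow(g),
                      density_mean = mean(g$density),
                      density_sd = stats::sd(g$density),
                      biomass_mean = mean(g$biomass),
                      biomass_sd = stats::sd(g$biomass),
                      metabolic_rate_mean = mean(g$mean_metabolic_rate),
                      metabolic_rate_sd = stats::sd(g$mean_metabolic_rate),
                      extinct_replicates = sum(g$extinct))
    if (has_control) {
      ctrl <- fin[fin$latitude == lat & fin$delta_t == 0, ]
      row$density_percent_change <-
        if (mean(ctrl$density) > 0)
          percent_change(mean(ctrl$density), mean(g$density)) else NA_real_
      row$biomass_percent_change <-
        if (mean(ctrl$biomass) > 0)
          percent_change(mean(ctrl$biomass), mean(g$biomass)) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  out$density_sd[is.na(out$density_sd)] <- 0
  out$biomass_sd[is.na(out$biomass_sd)] <- 0
  out$metabolic_rate_sd[is.na(out$metabolic_rate_sd)] <- 0
  out
}
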
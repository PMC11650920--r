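## Human-readable (YAML) configuration profiles: nested sections
## geometry / bioenergetics / mortality / experiment. Users with the
## original model's full parameter table can transcribe it into such a
## profile and load it here.

#' Read, write and validate a simulation configuration profile
#'
#' A profile is a YAML file with any of the nested sections `geometry`,
#' `bioenergetics`, `mortality` and `experiment`; keys within each
#' section are the argument names of [system_geometry()],
#' [bioenergetics_params()], [mortality_params()] and
#' [experiment_config()]. Missing keys fall back to the package
#' defaults; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a validated list with elements
#'   `geometry`, `params`, `mort` and `experiment_args` (a plain list
#'   of [experiment_config()] overrides). `validate_sim_config()`
#'   returns the same, or fails with an informative error.
#'   `write_sim_config()` invisibly returns `path`.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_sim_config(list(bioenergetics = list(q10_metabolism = 2.2)), path)
#' cfg <- read_sim_config(path)
#' cfg$params$q10_metabolism
#' @export
read_sim_config <- function(path) {
  validate_sim_config(yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @param config A nested list as found in a profile (for validation or
#'   writing).
#' @export
validate_sim_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  known <- c("geometry", "bioenergetics", "mortality", "experiment")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  check_keys <- function(section, fn, what) {
    if (is.null(section)) return(list())
    bad <- setdiff(names(section), names(formals(fn)))
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    section
  }
  gargs <- check_keys(config$geometry, system_geometry, "geometry")
  bargs <- check_keys(config$bioenergetics, bioenergetics_params,
                      "bioenergetics")
  margs <- check_keys(config$mortality, mortality_params, "mortality")
  eargs <- config$experiment
  if (!is.null(eargs)) {
    allowed <- setdiff(names(formals(experiment_config)),
                       c("params", "mort", "geometry"))
    bad <- setdiff(names(eargs), allowed)
    if (length(bad))
      stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  for (nm in c("breeding_season", "thermal_window"))
    if (!is.null(bargs[[nm]])) bargs[[nm]] <- unlist(bargs[[nm]])
  if (!is.null(gargs$grid_dim)) gargs$grid_dim <- unlist(gargs$grid_dim)
  list(geometry = do.call(system_geometry, gargs),
       params = do.call(bioenergetics_params, bargs),
       mort = do.call(mortality_params, margs),
       experiment_args = if (is.null(eargs)) list() else
         lapply(eargs, function(x) if (is.list(x)) unlist(x) else x))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}
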
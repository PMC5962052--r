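# YAML run configuration: loading with validation and defaults, exact
# round-tripping, and execution.

.default_output <- function() list(dir = "mtarray_out", stride = 1L,
                                   snapshot = TRUE, tracked = TRUE)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

.num_field <- function(x, key, default, where, min = -Inf) {
  v <- if (is.null(x[[key]])) default else x[[key]]
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min)
    stop(sprintf("invalid value for %s in %s", key, where), call. = FALSE)
  v
}

.parse_di <- function(x, where) {
  if (is.character(x) && length(x) == 1) return(di_preset(x))
  .check_keys(x, c("v_g_mean", "v_g_sd", "v_s_mean", "v_s_sd",
                   "k_c_mean", "k_c_sd", "k_r_mean", "k_r_sd"), where)
  for (k in names(x))
    if (!is.numeric(x[[k]]) || x[[k]] < 0)
      stop(sprintf("invalid value for %s in %s (must be a non-negative number)",
                   k, where), call. = FALSE)
  base <- di_preset("setA")
  do.call(di_params, modifyList(unclass(base), x))
}

.parse_stage <- function(x, i) {
  where <- sprintf("stages[%d]", i)
  .check_keys(x, c("duration", "preset", "di", "total_tubulin",
                   "nucleation", "zones", "noise", "dilution_factor",
                   "pinned_free"), where)
  if (is.null(x[["duration"]])) stop(where, " is missing 'duration'",
                                     call. = FALSE)
  di <- if (!is.null(x[["di"]])) .parse_di(x[["di"]], where)
  else di_preset(if (is.null(x[["preset"]])) "setA" else x[["preset"]])
  nuc <- if (is.null(x$nucleation)) nucleation_spec() else {
    .check_keys(x$nucleation, c("n_sites", "rate_per_site",
                                "concentration_dependent", "rate_slope"),
                paste0(where, "$nucleation"))
    nucleation_spec(
      n_sites = .num_field(x$nucleation, "n_sites", 500, where, min = 1),
      rate_per_site = .num_field(x$nucleation, "rate_per_site", 0.0005,
                                 where, min = 0),
      concentration_dependent =
        isTRUE(x$nucleation$concentration_dependent),
      rate_slope = .num_field(x$nucleation, "rate_slope", 0.0005 / 7,
                              where, min = 0))
  }
  zones <- if (is.null(x$zones)) NULL else {
    .check_keys(x$zones, c("peripheral_width", "interior_catastrophe_factor"),
                paste0(where, "$zones"))
    zone_spec(.num_field(x$zones, "peripheral_width", 3.75, where, min = 0),
              .num_field(x$zones, "interior_catastrophe_factor", 1 / 16,
                         where, min = 0))
  }
  noise <- if (is.null(x$noise)) noise_spec() else {
    .check_keys(x$noise, c("vary_v_s", "vary_k_c", "vary_k_r",
                           "radius_jitter_max"), paste0(where, "$noise"))
    noise_spec(isTRUE(x$noise$vary_v_s), isTRUE(x$noise$vary_k_c),
               isTRUE(x$noise$vary_k_r),
               .num_field(x$noise, "radius_jitter_max", 0, where, min = 0))
  }
  stage_spec(duration = x[["duration"]], di = di, nucleation = nuc,
             total_tubulin = x[["total_tubulin"]], zones = zones,
             noise = noise, dilution_factor = x[["dilution_factor"]],
             pinned_free = x[["pinned_free"]])
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (flat keys plus stage blocks), validates
#' every key, and fills the standard interphase defaults for anything
#' absent. An empty file yields the full default run: one 10,000 s Set A
#' stage, 35 uM total tubulin, 4 replicates.
#'
#' Top-level keys: `seed`, `replicates`, `dt`, `geometry` (radius, height,
#' volume), `kinetics` (k_on, c1), either `recipe` (+ optional `preset`)
#' or `stages` (list of blocks with `duration`, `preset` or `di`,
#' `total_tubulin`, `nucleation`, `zones`, `noise`, `dilution_factor`),
#' and `output` (dir, stride, snapshot, tracked). Unknown keys raise an
#' error naming the offender.
#'
#' @param path YAML file path.
#' @return an object of class `run_config`.
#' @seealso [write_config()] for the exact-round-trip inverse,
#'   [execute_config()] to run it.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' Build a run configuration from a plain list
#'
#' The programmatic equivalent of [load_config()]; see there for the
#' accepted keys.
#'
#' @param x a (possibly empty) named list.
#' @return an object of class `run_config`.
#' @export
as_run_config <- function(x = list()) {
  .check_keys(x, c("seed", "replicates", "dt", "geometry", "kinetics",
                   "recipe", "preset", "stages", "output"), "config")
  if (!is.null(x$recipe) && !is.null(x$stages))
    stop("config must set either 'recipe' or 'stages', not both",
         call. = FALSE)
  geometry <- if (is.null(x$geometry)) cell_geometry() else {
    .check_keys(x$geometry, c("radius", "height", "volume"), "geometry")
    cell_geometry(.num_field(x$geometry, "radius", 25, "geometry"),
                  .num_field(x$geometry, "height", 0.5, "geometry"),
                  if (is.null(x$geometry$volume)) NULL
                  else .num_field(x$geometry, "volume", NULL, "geometry"))
  }
  kinetics <- if (is.null(x$kinetics)) kinetic_constants() else {
    .check_keys(x$kinetics, c("k_on", "c1"), "kinetics")
    kinetic_constants(.num_field(x$kinetics, "k_on", 0.0167, "kinetics",
                                 min = 0),
                      .num_field(x$kinetics, "c1", 0, "kinetics", min = 0))
  }
  stages <- NULL
  if (!is.null(x$stages))
    stages <- lapply(seq_along(x$stages), function(i)
      .parse_stage(x$stages[[i]], i))
  else if (is.null(x$recipe))
    stages <- list(stage_spec(10000, di_preset("setA"), total_tubulin = 35))
  output <- modifyList(.default_output(),
                       if (is.null(x$output)) list() else x$output)
  .check_keys(output, names(.default_output()), "output")
  structure(list(
    seed = as.integer(.num_field(x, "seed", 1, "config")),
    replicates = as.integer(.num_field(x, "replicates", 4, "config",
                                       min = 1)),
    dt = .num_field(x, "dt", 1, "config", min = 1e-9),
    geometry = geometry, kinetics = kinetics,
    recipe = x$recipe,
    preset = if (is.null(x$preset)) "setA" else x$preset,
    stages = stages, output = output),
    class = "run_config")
}

.stage_to_list <- function(s) {
  out <- list(duration = s$duration, di = unclass(s$di),
              nucleation = unclass(s$nucleation))
  if (!is.null(s$total_tubulin)) out$total_tubulin <- s$total_tubulin
  if (!is.null(s$zones)) out$zones <- unclass(s$zones)
  out$noise <- unclass(s$noise)
  if (!is.null(s$dilution_factor)) out$dilution_factor <- s$dilution_factor
  if (!is.null(s$pinned_free)) out$pinned_free <- s$pinned_free
  out
}

#' Serialize a run configuration to YAML
#'
#' Writes the fully resolved configuration (all defaults made explicit,
#' including the seed), such that [load_config()] on the written file
#' reproduces the configuration exactly.
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  geom <- unclass(config$geometry)
  # a derived volume is omitted so reloading re-derives it exactly,
  # immune to decimal rounding in the YAML
  if (identical(geom$volume, pi * geom$radius^2 * geom$height))
    geom$volume <- NULL
  out <- list(seed = config$seed, replicates = config$replicates,
              dt = config$dt, geometry = geom,
              kinetics = config$kinetics[c("k_on", "c1")])
  if (!is.null(config$recipe)) {
    out$recipe <- config$recipe
    out$preset <- config$preset
  } else {
    out$stages <- lapply(config$stages, .stage_to_list)
  }
  out$output <- config$output
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Execute a run configuration
#'
#' Runs the configured recipe or stage list over all replicates
#' (replicate seeds are `seed`, `seed + 1`, ...) and returns per-condition
#' trajectories plus steady-state summaries.
#'
#' @param config a `run_config`.
#' @return an `mt_experiment` object.
#' @export
execute_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$recipe)) {
    rec <- recipe(config$recipe, preset = config$preset,
                  replicates = config$replicates)
    run_experiment(rec, config$kinetics, config$geometry,
                   seed = config$seed, dt = config$dt)
  } else {
    rec <- structure(list(name = "custom",
                          conditions = list(custom = config$stages),
                          replicates = config$replicates),
                     class = "mt_recipe")
    run_experiment(rec, config$kinetics, config$geometry,
                   seed = config$seed, dt = config$dt)
  }
}
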
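# Staged Monte Carlo engine: stage specifications, simulation state, and
# the multi-stage driver around the compiled per-second core.

#' One leg of a (possibly multi-stage) simulation protocol
#'
#' A stage fixes the dynamic-instability parameters, nucleation law, total
#' tubulin budget, optional zonal catastrophe landscape and noise model for
#' `duration` seconds. In multi-stage runs each later stage inherits the
#' full simulation state; `dilution_factor`, if present, multiplies the
#' tubulin budget at stage entry (physical dilution: polymer in excess of
#' the reduced budget is discarded as it depolymerizes until the balance
#' recovers).
#'
#' @param duration stage length, s (>= 1).
#' @param di a [di_params()] object (default interphase Set A).
#' @param nucleation a [nucleation_spec()]; set `rate_per_site = 0` for a
#'   nucleation-shutoff stage.
#' @param total_tubulin total tubulin budget, uM. `NULL` means "inherit
#'   from the previous stage" (35 uM for the first stage).
#' @param zones a [zone_spec()] or `NULL` (uniform catastrophe).
#' @param noise a [noise_spec()].
#' @param dilution_factor in (0, 1]; applied to the inherited budget at
#'   stage entry, or `NULL`.
#' @param pinned_free if non-`NULL`, the free tubulin concentration is held
#'   fixed at this value (uM) and the mass balance is disabled. Intended
#'   for validation against constant-concentration theory, not for cell
#'   simulations.
#' @return an object of class `stage_spec`.
#' @examples
#' # interphase assembly followed by nucleation shutoff
#' stages <- list(
#'   stage_spec(10000, di_preset("setB")),
#'   stage_spec(20000, di_preset("setB"),
#'              nucleation = nucleation_spec(rate_per_site = 0))
#' )
#' @export
stage_spec <- function(duration, di = di_preset("setA"),
                       nucleation = nucleation_spec(),
                       total_tubulin = NULL, zones = NULL,
                       noise = noise_spec(), dilution_factor = NULL,
                       pinned_free = NULL) {
  stopifnot(duration >= 1, inherits(di, "di_params"),
            inherits(nucleation, "nucleation_spec"),
            inherits(noise, "noise_spec"))
  if (!is.null(zones)) stopifnot(inherits(zones, "zone_spec"))
  if (!is.null(total_tubulin)) stopifnot(total_tubulin >= 0)
  if (!is.null(dilution_factor))
    if (!(dilution_factor > 0 && dilution_factor <= 1))
      stop("'dilution_factor' must be in (0, 1]")
  if (!is.null(pinned_free)) stopifnot(pinned_free >= 0)
  structure(list(duration = as.integer(duration), di = di,
                 nucleation = nucleation, total_tubulin = total_tubulin,
                 zones = zones, noise = noise,
                 dilution_factor = dilution_factor,
                 pinned_free = pinned_free),
            class = "stage_spec")
}

#' Simulation state of the microtubule array
#'
#' Per-site occupancy, length and phase, plus the tubulin budget. Mostly
#' constructed internally; exposed so interventions such as
#' [apply_dilution()] and engine validation against known initial
#' conditions are possible.
#'
#' @param n_sites number of nucleation sites.
#' @param lengths per-site MT length, um (0 for empty sites).
#' @param phases per-site phase: 0 empty, 1 growing, 2 shortening.
#' @param total_tubulin tubulin budget, uM.
#' @param t clock, s.
#' @param volume cytoplasmic volume, um^3 (for the derived free pool).
#' @param kinetics a [kinetic_constants()] object.
#' @return an object of class `mt_sim_state` with a derived `free_conc`.
#' @export
mt_sim_state <- function(n_sites = 500, lengths = numeric(n_sites),
                         phases = integer(n_sites), total_tubulin = 35,
                         t = 0, volume = 1000,
                         kinetics = kinetic_constants()) {
  stopifnot(length(lengths) == n_sites, length(phases) == n_sites,
            all(phases %in% 0:2), all(lengths >= 0), total_tubulin >= 0)
  if (any(lengths[phases == 0] != 0))
    stop("empty sites must have zero length")
  state <- structure(list(n_sites = as.integer(n_sites),
                          lengths = as.numeric(lengths),
                          phases = as.integer(phases),
                          total_tubulin = total_tubulin, t = t,
                          volume = volume, kinetics = kinetics),
                     class = "mt_sim_state")
  state$free_conc <- free_tubulin(total_tubulin, sum(state$lengths),
                                  volume, kinetics)
  state
}

#' Dilute the tubulin budget of an assembled array
#'
#' Scales the total tubulin budget by `factor` and recomputes the free pool
#' as `max(0, budget - polymer)`. While existing polymer exceeds the reduced
#' budget, the free pool is clamped at 0 (growth stops) and depolymerized
#' tubulin above the budget is discarded -- the semantics of physically
#' removing dimers from the cytoplasm. Microtubule lengths are unchanged.
#'
#' @param state an [mt_sim_state()].
#' @param factor dilution factor in (0, 1].
#' @return the diluted `mt_sim_state`.
#' @export
apply_dilution <- function(state, factor) {
  stopifnot(inherits(state, "mt_sim_state"))
  if (!(factor > 0 && factor <= 1))
    stop("'factor' must be in (0, 1]")
  state$total_tubulin <- state$total_tubulin * factor
  state$free_conc <- free_tubulin(state$total_tubulin, sum(state$lengths),
                                  state$volume, state$kinetics)
  state
}

#' Simulate a microtubule array through one or more stages
#'
#' Runs the fixed-step (default 1 s) Monte Carlo over all nucleation sites.
#' Each step: (1) the boundary radius is jittered if noise requests it;
#' (2) the growth velocity is computed once from the start-of-step free
#' tubulin (all MTs share it); (3) empty sites nucleate with probability
#' `1 - exp(-rate * dt)`, a new MT taking its first increment at the
#' parameter set's mean growth rate; (4) growing MTs elongate and either
#' undergo a forced catastrophe at the boundary (tip clamped to the radius)
#' or a stochastic one at the position-dependent frequency; (5) shortening
#' MTs shrink, vacate their site on complete depolymerization (re-opening
#' it for nucleation at the next step), or rescue; (6) the free pool is
#' reconciled once against the budget. Phase switches take effect on the
#' following step.
#'
#' @param stages a [stage_spec()] or list of them, executed in order; later
#'   stages inherit the full simulation state.
#' @param kinetics a [kinetic_constants()] object.
#' @param geometry a [cell_geometry()] object.
#' @param seed integer seed; if non-`NULL`, `set.seed(seed)` is called so
#'   the run is fully reproducible.
#' @param dt step duration, s (default 1).
#' @param init_state optional [mt_sim_state()] to start from instead of an
#'   empty array.
#' @return an object of class `mt_trajectory`: per-step series `time`,
#'   `n_mt`, `mean_length`, `free_conc` (including the t = 0 state), the
#'   tracked single-MT life history (`tracked_length`, with
#'   `tracked_n_mts` counting successive MTs at the tracked site), the
#'   final per-site snapshot, and stage boundary times.
#' @examples
#' traj <- simulate_mt_array(stage_spec(2000, di_preset("setB")), seed = 1)
#' summary(traj)
#' @export
simulate_mt_array <- function(stages, kinetics = kinetic_constants(),
                              geometry = cell_geometry(), seed = NULL,
                              dt = 1, init_state = NULL) {
  if (inherits(stages, "stage_spec")) stages <- list(stages)
  stopifnot(length(stages) >= 1,
            all(vapply(stages, inherits, logical(1), "stage_spec")),
            inherits(kinetics, "mt_kinetics"),
            inherits(geometry, "mt_geometry"), dt > 0)
  if (!is.null(seed)) set.seed(seed)

  n_sites <- stages[[1]]$nucleation$n_sites
  for (s in stages)
    if (s$nucleation$n_sites != n_sites)
      stop("all stages must use the same number of nucleation sites")

  if (is.null(init_state)) {
    budget <- if (is.null(stages[[1]]$total_tubulin)) 35
    else stages[[1]]$total_tubulin
    state <- mt_sim_state(n_sites, total_tubulin = budget,
                          volume = geometry$volume, kinetics = kinetics)
  } else {
    stopifnot(inherits(init_state, "mt_sim_state"),
              init_state$n_sites == n_sites)
    state <- init_state
    state$volume <- geometry$volume
    state$kinetics <- kinetics
  }

  time <- 0
  n_mt <- sum(state$phases != 0)
  occ <- state$phases != 0
  mean_length <- if (n_mt > 0) mean(state$lengths[occ]) else NA_real_
  free0 <- if (!is.null(stages[[1]]$pinned_free)) stages[[1]]$pinned_free
  else free_tubulin(state$total_tubulin, sum(state$lengths),
                    geometry$volume, kinetics)
  free_conc <- free0
  tracked_length <- 0
  # track the first site to nucleate; when starting from a pre-assembled
  # state, the first occupied site
  tracked_site <- -1L
  tracked_n_mts <- 0L
  if (any(state$phases != 0)) {
    tracked_site <- which(state$phases != 0)[1] - 1L
    tracked_n_mts <- 1L
    tracked_length <- state$lengths[tracked_site + 1L]
  }
  stage_ends <- numeric(0)
  t_now <- 0

  for (si in seq_along(stages)) {
    sg <- stages[[si]]
    if (!is.null(sg$total_tubulin)) state$total_tubulin <- sg$total_tubulin
    if (!is.null(sg$dilution_factor))
      state <- apply_dilution(state, sg$dilution_factor)
    zones_on <- !is.null(sg$zones)
    if (zones_on && sg$zones$peripheral_width > geometry$radius)
      stop("peripheral zone wider than the cell radius")
    if (sg$noise$radius_jitter_max >= geometry$radius)
      stop("radius jitter must be smaller than the cell radius")
    res <- .run_stage_cpp(
      state$lengths, state$phases, state$total_tubulin,
      sg$duration, dt,
      sg$di$v_g_mean, sg$di$v_s_mean, sg$di$v_s_sd,
      sg$di$k_c_mean, sg$di$k_r_mean,
      sg$nucleation$rate_per_site, sg$nucleation$concentration_dependent,
      sg$nucleation$rate_slope,
      kinetics$k_on, kinetics$c1,
      kinetics$dimers_per_um, kinetics$dimers_per_uM_um3,
      geometry$radius, geometry$volume,
      zones_on,
      if (zones_on) sg$zones$peripheral_width else 0,
      if (zones_on) sg$zones$interior_catastrophe_factor else 1,
      sg$noise$vary_v_s, sg$noise$vary_k_c, sg$noise$vary_k_r,
      sg$noise$radius_jitter_max,
      if (is.null(sg$pinned_free)) -1 else sg$pinned_free,
      tracked_site, tracked_n_mts)
    state$lengths <- res$lengths
    state$phases <- res$phases
    tracked_site <- res$tracked_site
    tracked_n_mts <- res$tracked_n_mts
    time <- c(time, t_now + seq_len(sg$duration) * dt)
    n_mt <- c(n_mt, res$n_mt)
    mean_length <- c(mean_length, res$mean_length)
    free_conc <- c(free_conc, res$free_conc)
    tracked_length <- c(tracked_length, res$tracked_length)
    t_now <- t_now + sg$duration * dt
    stage_ends <- c(stage_ends, t_now)
  }
  state$t <- t_now
  state$free_conc <- free_conc[length(free_conc)]

  structure(list(time = time, n_mt = n_mt, mean_length = mean_length,
                 free_conc = free_conc, tracked_length = tracked_length,
                 tracked_site = if (tracked_site >= 0) tracked_site + 1L
                 else NA_integer_,
                 tracked_n_mts = tracked_n_mts,
                 final_lengths = state$lengths,
                 final_phases = state$phases,
                 final_state = state,
                 stage_ends = stage_ends, dt = dt, seed = seed,
                 n_sites = n_sites, geometry = geometry,
                 kinetics = kinetics),
            class = "mt_trajectory")
}
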
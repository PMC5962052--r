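# Dynamic-instability parameter sets, rate->probability conversion,
# concentration-dependent laws, zonal catastrophe, per-step noise.

#' Dynamic instability parameters for one cell state
#'
#' Means and standard deviations of the four plus-end parameters: growth
#' velocity `v_g`, shortening velocity `v_s` (um/s), catastrophe frequency
#' `k_c` and rescue frequency `k_r` (s^-1). The sds are used only by the
#' per-step noise model ([noise_spec()]); the baseline engine runs on means.
#'
#' @param v_g_mean,v_g_sd growth velocity mean and sd, um/s.
#' @param v_s_mean,v_s_sd shortening velocity mean and sd, um/s.
#' @param k_c_mean,k_c_sd catastrophe frequency mean and sd, s^-1.
#' @param k_r_mean,k_r_sd rescue frequency mean and sd, s^-1.
#' @return an object of class `di_params`.
#' @seealso [di_preset()] for the published LLCPK1 parameter sets.
#' @export
di_params <- function(v_g_mean, v_s_mean, k_c_mean, k_r_mean,
                      v_g_sd = 0, v_s_sd = 0, k_c_sd = 0, k_r_sd = 0) {
  vals <- c(v_g_mean, v_s_mean, k_c_mean, k_r_mean,
            v_g_sd, v_s_sd, k_c_sd, k_r_sd)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("dynamic instability means and sds must be finite and non-negative")
  structure(list(v_g_mean = v_g_mean, v_g_sd = v_g_sd,
                 v_s_mean = v_s_mean, v_s_sd = v_s_sd,
                 k_c_mean = k_c_mean, k_c_sd = k_c_sd,
                 k_r_mean = k_r_mean, k_r_sd = k_r_sd),
            class = "di_params")
}

# Published plus-end dynamics measured in LLCPK1 epithelial cells:
# two interphase sets (A, B) and the prophase/NEBD set.
.di_presets <- list(
  setA = list(v_g = c(0.192, 0.123), v_s = c(0.218, 0.144),
              k_c = c(0.026, 0.024), k_r = c(0.175, 0.104)),
  setB = list(v_g = c(0.142, 0.097), v_s = c(0.188, 0.132),
              k_c = c(0.053, 0.003), k_r = c(0.086, 0.005)),
  nebd = list(v_g = c(0.178, 0.153), v_s = c(0.205, 0.087),
              k_c = c(0.075, 0.089), k_r = c(0.023, 0.029))
)

#' Published dynamic-instability parameter presets
#'
#' Returns measured plus-end parameters for LLCPK1 cells: `"setA"` and
#' `"setB"` are two independent interphase measurements; `"nebd"` is the
#' prophase set measured around nuclear envelope breakdown (3-fold higher
#' catastrophe, 7.5-fold lower rescue than interphase Set A).
#'
#' @param name one of `"setA"`, `"setB"`, `"nebd"`.
#' @return a [di_params()] object.
#' @examples
#' di_preset("setB")
#' @export
di_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.di_presets))
    stop("unknown preset; valid names: ",
         paste(names(.di_presets), collapse = ", "))
  p <- .di_presets[[name]]
  di_params(v_g_mean = p$v_g[1], v_g_sd = p$v_g[2],
            v_s_mean = p$v_s[1], v_s_sd = p$v_s[2],
            k_c_mean = p$k_c[1], k_c_sd = p$k_c[2],
            k_r_mean = p$k_r[1], k_r_sd = p$k_r[2])
}

#' Nucleation specification
#'
#' A fixed pool of central nucleation sites, each nucleating a new
#' microtubule as a first-order process. Optionally the per-site rate is a
#' linear function of free tubulin (`rate_slope * free_conc`); the default
#' slope recovers the measured interphase rate (0.0005 s^-1) at the
#' measured interphase free concentration (7 uM).
#'
#' @param n_sites number of nucleation sites (default 500); also the
#'   maximum number of microtubules.
#' @param rate_per_site nucleation rate per empty site, s^-1
#'   (default 0.0005).
#' @param concentration_dependent if `TRUE`, the rate is
#'   `rate_slope * free_conc` instead of the constant.
#' @param rate_slope slope of the linear nucleation law, s^-1 uM^-1.
#' @return an object of class `nucleation_spec`.
#' @export
nucleation_spec <- function(n_sites = 500, rate_per_site = 0.0005,
                            concentration_dependent = FALSE,
                            rate_slope = 0.0005 / 7) {
  stopifnot(n_sites >= 1, rate_per_site >= 0, rate_slope >= 0,
            is.logical(concentration_dependent))
  structure(list(n_sites = as.integer(n_sites),
                 rate_per_site = rate_per_site,
                 concentration_dependent = concentration_dependent,
                 rate_slope = rate_slope),
            class = "nucleation_spec")
}

#' Two-zone catastrophe landscape
#'
#' Splits the cell into a stabilizing interior and a dynamic peripheral
#' annulus: tips strictly inside `radius - peripheral_width` experience
#' `k_c * interior_catastrophe_factor` (default 1/16, the measured 16-fold
#' interior reduction); tips at or beyond the seam use the full measured
#' frequency. Rescue is identical in both zones.
#'
#' @param peripheral_width width of the outer dynamic zone, um.
#' @param interior_catastrophe_factor multiplier on `k_c` in the interior,
#'   in (0, 1].
#' @return an object of class `zone_spec`.
#' @export
zone_spec <- function(peripheral_width, interior_catastrophe_factor = 1 / 16) {
  stopifnot(peripheral_width >= 0,
            interior_catastrophe_factor > 0,
            interior_catastrophe_factor <= 1)
  structure(list(peripheral_width = peripheral_width,
                 interior_catastrophe_factor = interior_catastrophe_factor),
            class = "zone_spec")
}

#' Per-step parameter and boundary noise
#'
#' When flagged, the shortening velocity is redrawn each step for each MT
#' uniformly on `[mean - sd, mean + sd]` (truncated at 0), and catastrophe/
#' rescue frequencies uniformly on `[0, 2 * mean]` -- the widest symmetric
#' range that stays non-negative. The boundary radius is reduced by a single
#' global draw `U(0, radius_jitter_max)` per step.
#'
#' @param vary_v_s,vary_k_c,vary_k_r logical flags enabling per-MT per-step
#'   resampling of the corresponding parameter.
#' @param radius_jitter_max maximum random reduction of the boundary
#'   radius, um (default 0; the published experiment uses 3).
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(vary_v_s = FALSE, vary_k_c = FALSE, vary_k_r = FALSE,
                       radius_jitter_max = 0) {
  stopifnot(is.logical(vary_v_s), is.logical(vary_k_c), is.logical(vary_k_r),
            radius_jitter_max >= 0)
  structure(list(vary_v_s = vary_v_s, vary_k_c = vary_k_c,
                 vary_k_r = vary_k_r,
                 radius_jitter_max = radius_jitter_max),
            class = "noise_spec")
}

#' Growth velocity from free tubulin
#'
#' `v_g = k_on * free_conc + c1`.
#'
#' @param free_conc free tubulin, uM (vectorized).
#' @param kinetics a [kinetic_constants()] object.
#' @return growth velocity, um/s.
#' @export
growth_velocity <- function(free_conc, kinetics = kinetic_constants()) {
  if (any(free_conc < 0)) stop("'free_conc' must be non-negative")
  kinetics$k_on * free_conc + kinetics$c1
}

#' Per-step transition probability of a first-order rate
#'
#' `1 - exp(-rate * dt)`: the probability that at least one event of a
#' Poisson process of the given rate falls inside one step. At the model's
#' magnitudes (rates <= 0.175 s^-1, dt = 1 s) this differs from the naive
#' `rate * dt` by under 1 percent, and remains a valid probability for any
#' rate or step size.
#'
#' @param rate first-order rate, s^-1 (vectorized).
#' @param dt step duration, s.
#' @return probability in \[0, 1).
#' @export
transition_probability <- function(rate, dt = 1) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  if (any(dt <= 0)) stop("'dt' must be positive")
  1 - exp(-rate * dt)
}

#' Position-dependent catastrophe frequency
#'
#' Applies the two-zone landscape of [zone_spec()] to a tip at a given
#' radial position; with `zones = NULL` the frequency is uniform.
#'
#' @param tip_radius radial position of the plus end, um (vectorized).
#' @param cell_radius cell radius, um.
#' @param zones a [zone_spec()] or `NULL`.
#' @param k_c baseline catastrophe frequency, s^-1.
#' @return effective catastrophe frequency, s^-1.
#' @export
effective_catastrophe_rate <- function(tip_radius, cell_radius,
                                       zones = NULL, k_c) {
  if (any(tip_radius < 0) || any(tip_radius > cell_radius))
    stop("tip position outside [0, cell_radius]")
  if (is.null(zones)) return(rep_len(k_c, length(tip_radius)))
  stopifnot(inherits(zones, "zone_spec"),
            zones$peripheral_width <= cell_radius)
  seam <- cell_radius - zones$peripheral_width
  ifelse(tip_radius < seam, k_c * zones$interior_catastrophe_factor, k_c)
}

#' Per-site nucleation rate
#'
#' Constant, or linear in free tubulin when the spec is
#' concentration-dependent.
#'
#' @param free_conc free tubulin, uM (vectorized).
#' @param spec a [nucleation_spec()].
#' @return nucleation rate per site, s^-1.
#' @export
nucleation_rate <- function(free_conc, spec = nucleation_spec()) {
  if (any(free_conc < 0)) stop("'free_conc' must be non-negative")
  stopifnot(inherits(spec, "nucleation_spec"))
  if (spec$concentration_dependent) spec$rate_slope * free_conc
  else rep_len(spec$rate_per_site, length(free_conc))
}

#' Sample one step's effective dynamics parameters
#'
#' Draws the per-step noisy values of `v_s`, `k_c`, `k_r` for `n`
#' microtubules under a [noise_spec()]; unflagged parameters are returned
#' at their means. This mirrors exactly what the engine does internally
#' each step.
#'
#' @param di a [di_params()] object.
#' @param noise a [noise_spec()] object.
#' @param n number of draws (microtubules).
#' @return a list with numeric vectors `v_s`, `k_c`, `k_r` of length `n`.
#' @export
sample_step_params <- function(di, noise = noise_spec(), n = 1) {
  stopifnot(inherits(di, "di_params"), inherits(noise, "noise_spec"), n >= 1)
  v_s <- if (noise$vary_v_s)
    runif(n, max(0, di$v_s_mean - di$v_s_sd), di$v_s_mean + di$v_s_sd)
  else rep(di$v_s_mean, n)
  k_c <- if (noise$vary_k_c) runif(n, 0, 2 * di$k_c_mean)
  else rep(di$k_c_mean, n)
  k_r <- if (noise$vary_k_r) runif(n, 0, 2 * di$k_r_mean)
  else rep(di$k_r_mean, n)
  list(v_s = v_s, k_c = k_c, k_r = k_r)
}

#' @export
print.di_params <- function(x, ...) {
  cat("Dynamic instability parameters:\n")
  cat(sprintf("  v_g %g +/- %g um/s   v_s %g +/- %g um/s\n",
              x$v_g_mean, x$v_g_sd, x$v_s_mean, x$v_s_sd))
  cat(sprintf("  k_c %g +/- %g s^-1   k_r %g +/- %g s^-1\n",
              x$k_c_mean, x$k_c_sd, x$k_r_mean, x$k_r_sd))
  invisible(x)
}
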
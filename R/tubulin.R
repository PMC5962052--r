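# Tubulin mass accounting: exact bookkeeping between concentration (uM),
# dimer counts and polymer length (um), closing the monomer-polymer balance.

# Avogadro-derived conversion: molecules per (uM * um^3)
# N_A * 1e-6 mol/L * 1e-15 L/um^3 = 6.02214076e23 * 1e-21
DIMERS_PER_UM_UM3 <- 602.214076

#' Kinetic constants for microtubule growth
#'
#' Growth velocity is a linear function of the free tubulin concentration,
#' `v_g = k_on * [Tub] + c1`. The lattice packing constant converts polymer
#' length to tubulin dimers: 1 um of microtubule contains 1624 dimers.
#'
#' @param k_on apparent on-rate constant, um uM^-1 s^-1 (default 0.0167,
#'   i.e. 1/60 um/s per uM as measured in LLCPK1 cells).
#' @param c1 growth-velocity intercept at zero free tubulin, um/s
#'   (default 0).
#' @param dimers_per_um tubulin dimers per um of lattice (1624).
#' @param dimers_per_uM_um3 molecules per (uM um^3), the Avogadro-derived
#'   unit bridge (about 602.214).
#' @return an object of class `mt_kinetics`.
#' @examples
#' kin <- kinetic_constants()
#' growth_velocity(7, kin)  # ~0.117 um/s at interphase free tubulin
#' @export
kinetic_constants <- function(k_on = 0.0167, c1 = 0,
                              dimers_per_um = 1624,
                              dimers_per_uM_um3 = DIMERS_PER_UM_UM3) {
  stopifnot(k_on >= 0, c1 >= 0, dimers_per_um > 0, dimers_per_uM_um3 > 0)
  structure(list(k_on = k_on, c1 = c1, dimers_per_um = dimers_per_um,
                 dimers_per_uM_um3 = dimers_per_uM_um3),
            class = "mt_kinetics")
}

#' Cell geometry
#'
#' The simulated cell is a thin cylinder mimicking the basal section of an
#' adherent cell. By default the volume is derived as
#' `pi * radius^2 * height` (about 982 um^3 for the 25 um x 0.5 um default
#' cell, often rounded to "approximately 1000 um^3"); pass `volume`
#' explicitly to override, e.g. `volume = 1000`.
#'
#' @param radius cell radius, um (default 25).
#' @param height cylinder height, um (default 0.5).
#' @param volume cytoplasmic volume, um^3; `NULL` (default) derives it
#'   from radius and height.
#' @return an object of class `mt_geometry`.
#' @export
cell_geometry <- function(radius = 25, height = 0.5, volume = NULL) {
  stopifnot(radius > 0, height > 0)
  if (is.null(volume)) volume <- pi * radius^2 * height
  stopifnot(volume > 0)
  structure(list(radius = radius, height = height, volume = volume),
            class = "mt_geometry")
}

#' Convert tubulin concentration to a dimer count
#'
#' @param conc concentration, uM (>= 0).
#' @param volume volume, um^3 (> 0).
#' @param dimers_per_uM_um3 unit bridge, molecules per (uM um^3).
#' @return number of dimers (a real number; the model is coarse-grained and
#'   does not round to integer molecules).
#' @export
concentration_to_dimers <- function(conc, volume,
                                    dimers_per_uM_um3 = DIMERS_PER_UM_UM3) {
  if (any(conc < 0)) stop("'conc' must be non-negative")
  if (any(volume <= 0)) stop("'volume' must be positive")
  conc * dimers_per_uM_um3 * volume
}

#' Convert a dimer count to a tubulin concentration
#'
#' Inverse of [concentration_to_dimers()].
#'
#' @param dimers number of dimers (>= 0).
#' @inheritParams concentration_to_dimers
#' @return concentration, uM.
#' @export
dimers_to_concentration <- function(dimers, volume,
                                    dimers_per_uM_um3 = DIMERS_PER_UM_UM3) {
  if (any(dimers < 0)) stop("'dimers' must be non-negative")
  if (any(volume <= 0)) stop("'volume' must be positive")
  dimers / (dimers_per_uM_um3 * volume)
}

#' Tubulin concentration equivalent of assembled polymer
#'
#' Converts total microtubule length to the concentration of tubulin dimers
#' locked in polymer, using the 1624 dimers/um lattice constant.
#'
#' @param total_length summed microtubule length, um (>= 0).
#' @param volume cytoplasmic volume, um^3.
#' @param kinetics a [kinetic_constants()] object supplying the conversion
#'   constants.
#' @return polymerized tubulin, uM.
#' @examples
#' # 411 MTs of 20.3 um in 1000 um^3 lock up ~22.5 uM of a 35 uM pool
#' polymer_concentration(411 * 20.3, 1000)
#' @export
polymer_concentration <- function(total_length, volume = 1000,
                                  kinetics = kinetic_constants()) {
  if (any(total_length < 0)) stop("'total_length' must be non-negative")
  if (any(volume <= 0)) stop("'volume' must be positive")
  total_length * kinetics$dimers_per_um /
    (kinetics$dimers_per_uM_um3 * volume)
}

#' Free tubulin under the closed mass balance
#'
#' The free pool is a derived quantity: total budget minus the polymer
#' equivalent, clamped at zero. The clamp is only reachable after a dilution
#' intervention leaves more polymer than the reduced budget.
#'
#' @param total_conc total tubulin budget, uM.
#' @param total_polymer_length summed microtubule length, um.
#' @inheritParams polymer_concentration
#' @return free tubulin, uM.
#' @export
free_tubulin <- function(total_conc, total_polymer_length, volume = 1000,
                         kinetics = kinetic_constants()) {
  if (any(total_conc < 0)) stop("'total_conc' must be non-negative")
  pmax(0, total_conc -
         polymer_concentration(total_polymer_length, volume, kinetics))
}

#' @export
print.mt_kinetics <- function(x, ...) {
  cat("Microtubule growth kinetics\n")
  cat(sprintf("  v_g = %g * [Tub] + %g um/s;  %g dimers/um\n",
              x$k_on, x$c1, x$dimers_per_um))
  invisible(x)
}

#' @export
print.mt_geometry <- function(x, ...) {
  cat(sprintf("Cell geometry: radius %g um, height %g um, volume %g um^3\n",
              x$radius, x$height, x$volume))
  invisible(x)
}
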
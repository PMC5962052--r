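# Shared fixtures built in code.

# conversion used by independent arithmetic oracles in tests
UM3_UM_CONV <- 602.214076

# deterministic single-MT scenario: one occupied site, fixed growth speed
# (k_on = 0 so the free pool does not influence velocity), no stochastic
# transitions unless the caller sets them
one_mt_state <- function(length, phase, n_sites = 500, total_tubulin = 35,
                         volume = 1000, kinetics = kinetic_constants()) {
  lens <- numeric(n_sites)
  phs <- integer(n_sites)
  lens[1] <- length
  phs[1] <- phase
  mt_sim_state(n_sites, lens, phs, total_tubulin = total_tubulin,
               volume = volume, kinetics = kinetics)
}

quiet_di <- function(v_g = 0, v_s = 0, k_c = 0, k_r = 0)
  di_params(v_g_mean = v_g, v_s_mean = v_s, k_c_mean = k_c, k_r_mean = k_r)

no_nucleation <- nucleation_spec(rate_per_site = 0)

# check mass balance along a recorded trajectory (uM budget vs
# free + polymer-equivalent reconstructed from n_mt and mean length)
expect_mass_conserved <- function(traj, budget, volume, tol = 1e-9) {
  poly_per_um <- 1624 / (UM3_UM_CONV * volume)
  n <- traj$n_mt
  ml <- ifelse(is.na(traj$mean_length), 0, traj$mean_length)
  total <- traj$free_conc + n * ml * poly_per_um
  expect_lt(max(abs(total - budget)) / budget, tol)
}
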
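# Step semantics, staged protocols, conservation, determinism.

test_that("a growing MT reaching the boundary is clamped and switches", {
  # fixed growth speed 0.20 um/s regardless of the pool (k_on = 0)
  kin <- kinetic_constants(k_on = 0, c1 = 0.2)
  st <- one_mt_state(24.95, 1L, kinetics = kin)
  tr <- simulate_mt_array(
    stage_spec(1, quiet_di(v_s = 0.188), nucleation = no_nucleation),
    kinetics = kin, geometry = cell_geometry(volume = 1000),
    seed = 1, init_state = st)
  expect_equal(tr$final_lengths[1], 25)
  expect_equal(tr$final_phases[1], 2L)
})

test_that("complete depolymerization frees the site and returns the mass", {
  st <- one_mt_state(0.15, 2L)
  tr <- simulate_mt_array(
    stage_spec(1, quiet_di(v_s = 0.188), nucleation = no_nucleation),
    geometry = cell_geometry(volume = 1000), seed = 1, init_state = st)
  expect_equal(tr$final_phases[1], 0L)
  expect_equal(tr$n_mt, c(1L, 0L))
  # the 0.15 um (~243.6 dimers) are back in the pool: free == budget
  expect_equal(tr$free_conc[2], 35, tolerance = 1e-12)
})

test_that("with nucleation off the empty state is absorbing", {
  tr <- simulate_mt_array(
    stage_spec(50, di_preset("setA"), nucleation = no_nucleation),
    seed = 1)
  expect_true(all(tr$n_mt == 0))
  expect_true(all(tr$free_conc == 35))
  expect_equal(tr$time, 0:50)
})

test_that("phase changes act on the following step (move-then-test)", {
  # shortening MT with certain rescue: it still shrinks in the rescue step
  # and only grows from the next one
  kin <- kinetic_constants(k_on = 0, c1 = 0.1)
  st <- one_mt_state(5, 2L, kinetics = kin)
  di <- quiet_di(v_s = 0.2, k_r = 1e9)  # rescue probability ~ 1
  tr <- simulate_mt_array(stage_spec(2, di, nucleation = no_nucleation),
                          kinetics = kin,
                          geometry = cell_geometry(volume = 1000),
                          seed = 1, init_state = st)
  expect_equal(tr$tracked_length, c(5, 4.8, 4.9), tolerance = 1e-12)
})

test_that("mass is conserved at every recorded step", {
  geom <- cell_geometry()
  tr <- simulate_mt_array(stage_spec(3000, di_preset("setB")),
                          geometry = geom, seed = 5)
  expect_mass_conserved(tr, 35, geom$volume)
  # also under zones, noise and a lower budget
  tr2 <- simulate_mt_array(
    stage_spec(1500, di_preset("setB"), total_tubulin = 25,
               zones = zone_spec(3.75),
               noise = noise_spec(vary_v_s = TRUE, vary_k_c = TRUE,
                                  vary_k_r = TRUE, radius_jitter_max = 3)),
    geometry = geom, seed = 6)
  expect_mass_conserved(tr2, 25, geom$volume)
})

test_that("trajectories are reproducible from the seed and arrays line up", {
  stg <- list(stage_spec(500, di_preset("setB")),
              stage_spec(300, di_preset("nebd")))
  a <- simulate_mt_array(stg, seed = 11)
  b <- simulate_mt_array(stg, seed = 11)
  expect_identical(a[c("n_mt", "mean_length", "free_conc",
                       "tracked_length", "final_lengths")],
                   b[c("n_mt", "mean_length", "free_conc",
                       "tracked_length", "final_lengths")])
  c <- simulate_mt_array(stg, seed = 12)
  expect_false(identical(a$n_mt, c$n_mt))
  expect_length(a$time, 801)
  expect_length(a$n_mt, 801)
  expect_length(a$free_conc, 801)
  expect_equal(a$stage_ends, c(500, 800))
})

test_that("occupancy stays within the site pool and lengths in bounds", {
  geom <- cell_geometry()
  tr <- simulate_mt_array(stage_spec(4000, di_preset("setA")),
                          geometry = geom, seed = 3)
  expect_true(all(tr$n_mt <= tr$n_sites))
  occ <- tr$final_phases != 0
  expect_true(all(tr$final_lengths[occ] > 0))
  expect_true(all(tr$final_lengths[occ] <= geom$radius))
  # nucleation off: the MT count can only fall
  tr2 <- simulate_mt_array(
    list(stage_spec(2000, di_preset("setB")),
         stage_spec(2000, di_preset("setB"), nucleation = no_nucleation)),
    geometry = geom, seed = 4)
  sel <- tr2$time >= 2000
  expect_true(all(diff(tr2$n_mt[sel]) <= 0))
})

test_that("the tracked site is the first to nucleate and its history spans MTs", {
  tr <- simulate_mt_array(stage_spec(3000, di_preset("setB")), seed = 2)
  expect_false(is.na(tr$tracked_site))
  expect_gte(tr$tracked_n_mts, 1L)
  first_nuc <- which(tr$n_mt > 0)[1]
  expect_gt(tr$tracked_length[first_nuc], 0)
  expect_true(all(tr$tracked_length >= 0))
})

test_that("dilution rescales the budget, clamps the pool, keeps lengths", {
  geom <- cell_geometry()
  tr1 <- simulate_mt_array(stage_spec(8000, di_preset("setB")),
                           geometry = geom, seed = 9)
  st <- tr1$final_state
  expect_equal(apply_dilution(st, 1)$free_conc, st$free_conc)
  d <- apply_dilution(st, 0.1)
  expect_equal(d$total_tubulin, st$total_tubulin * 0.1)
  expect_identical(d$free_conc, 0)  # assembled polymer exceeds 3.5 uM
  expect_identical(d$lengths, st$lengths)
  expect_error(apply_dilution(st, 0), "factor")
  expect_error(apply_dilution(st, 1.5), "factor")
  # in-protocol: growth stops immediately (v_g = 0 at free = 0), MTs shrink
  tr2 <- simulate_mt_array(
    list(stage_spec(8000, di_preset("setB")),
         stage_spec(600, di_preset("setB"), dilution_factor = 0.1)),
    geometry = geom, seed = 9)
  i1 <- which(tr2$time == 8000)
  expect_equal(tr2$free_conc[i1 + 1], 0)
  expect_lt(tr2$mean_length[length(tr2$time)], tr2$mean_length[i1])
})

test_that("a pinned free pool bypasses the mass balance", {
  geom <- cell_geometry(radius = Inf, volume = 1000)
  tr <- simulate_mt_array(
    stage_spec(400, di_preset("nebd"), pinned_free = 7,
               nucleation = nucleation_spec(rate_per_site = 0.01)),
    geometry = geom, seed = 8)
  expect_true(all(tr$free_conc == 7))
  expect_gt(max(tr$n_mt), 0)
})
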
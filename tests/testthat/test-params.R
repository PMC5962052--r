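# Parameter presets, probability conversion, concentration laws, zones,
# and per-step noise sampling.

test_that("presets return the published LLCPK1 values verbatim", {
  a <- di_preset("setA")
  expect_equal(unlist(a[c("v_g_mean", "v_g_sd")]), c(v_g_mean = 0.192, v_g_sd = 0.123))
  expect_equal(unlist(a[c("v_s_mean", "v_s_sd")]), c(v_s_mean = 0.218, v_s_sd = 0.144))
  expect_equal(unlist(a[c("k_c_mean", "k_c_sd")]), c(k_c_mean = 0.026, k_c_sd = 0.024))
  expect_equal(unlist(a[c("k_r_mean", "k_r_sd")]), c(k_r_mean = 0.175, k_r_sd = 0.104))
  b <- di_preset("setB")
  expect_equal(c(b$v_g_mean, b$v_s_mean, b$k_c_mean, b$k_r_mean),
               c(0.142, 0.188, 0.053, 0.086))
  expect_equal(c(b$v_g_sd, b$v_s_sd, b$k_c_sd, b$k_r_sd),
               c(0.097, 0.132, 0.003, 0.005))
  n <- di_preset("nebd")
  expect_equal(c(n$v_g_mean, n$v_s_mean, n$k_c_mean, n$k_r_mean),
               c(0.178, 0.205, 0.075, 0.023))
  expect_equal(c(n$v_g_sd, n$v_s_sd, n$k_c_sd, n$k_r_sd),
               c(0.153, 0.087, 0.089, 0.029))
  expect_error(di_preset("setC"), "setA.*setB.*nebd")
})

test_that("growth velocity is linear in free tubulin", {
  expect_equal(growth_velocity(7), 0.1169)
  expect_equal(growth_velocity(12.5), 0.20875)
  expect_identical(growth_velocity(0), 0)
  expect_equal(growth_velocity(10, kinetic_constants(k_on = 0.02, c1 = 0.01)),
               0.21)
  expect_error(growth_velocity(-1), "non-negative")
})

test_that("rate -> per-step probability is exponential, bounded by rate*dt", {
  # frozen closed-form values
  expect_equal(transition_probability(0.0005, 1), 0.0004998750,
               tolerance = 1e-6)
  expect_equal(transition_probability(0.026, 1), 0.02566489,
               tolerance = 1e-6)
  expect_identical(transition_probability(0, 1), 0)
  rates <- c(0, 1e-4, 0.01, 0.1, 0.5, 2)
  for (dt in c(0.1, 1, 5)) {
    p <- transition_probability(rates, dt)
    expect_true(all(p >= 0 & p < 1))
    expect_true(all(diff(p) > 0))          # monotone in rate
    expect_true(all(p <= rates * dt))      # never above the linear bound
  }
  expect_true(all(transition_probability(0.05, c(1, 2, 4)) ==
                    cummax(transition_probability(0.05, c(1, 2, 4)))))
})

test_that("zonal catastrophe landscape stabilizes the interior only", {
  z <- zone_spec(peripheral_width = 3.75)
  expect_equal(effective_catastrophe_rate(10, 25, z, 0.053), 0.053 / 16)
  expect_equal(effective_catastrophe_rate(24, 25, z, 0.053), 0.053)
  # the seam itself is peripheral
  expect_equal(effective_catastrophe_rate(25 - 3.75, 25, z, 0.053), 0.053)
  expect_equal(effective_catastrophe_rate(10, 25, NULL, 0.053), 0.053)
  # full-width peripheral zone recapitulates the unzoned model everywhere
  zf <- zone_spec(peripheral_width = 25)
  r <- seq(0, 25, by = 0.5)
  expect_equal(effective_catastrophe_rate(r, 25, zf, 0.053),
               rep(0.053, length(r)))
  expect_error(effective_catastrophe_rate(26, 25, z, 0.053), "outside")
})

test_that("nucleation law: constant, or linear through the origin", {
  expect_equal(nucleation_rate(c(0, 7, 20)), rep(0.0005, 3))
  lin <- nucleation_spec(concentration_dependent = TRUE)
  expect_identical(nucleation_rate(0, lin), 0)
  # default slope calibrated to recover the measured interphase rate at
  # the measured 7 uM interphase free tubulin
  expect_equal(nucleation_rate(7, lin), 0.0005)
  expect_equal(nucleation_rate(14, lin), 0.001)
})

test_that("noise sampling covers the stated ranges and preserves means", {
  di <- di_preset("setB")
  still <- sample_step_params(di, noise_spec(), n = 10)
  expect_equal(still$v_s, rep(0.188, 10))
  expect_equal(still$k_c, rep(0.053, 10))
  expect_equal(still$k_r, rep(0.086, 10))

  set.seed(99)
  n <- 1e5
  s <- sample_step_params(di, noise_spec(vary_v_s = TRUE, vary_k_c = TRUE,
                                         vary_k_r = TRUE), n = n)
  expect_true(all(s$v_s >= 0.188 - 0.132 & s$v_s <= 0.188 + 0.132))
  expect_true(all(s$k_c >= 0 & s$k_c <= 2 * 0.053))
  expect_true(all(s$k_r >= 0 & s$k_r <= 2 * 0.086))
  # uniform ranges are symmetric about the mean: 3 standard errors
  se_kc <- (2 * 0.053 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(s$k_c) - 0.053), 3 * se_kc)
  se_vs <- (2 * 0.132 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mean(s$v_s) - 0.188), 3 * se_vs)
})
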
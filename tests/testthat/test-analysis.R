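# Steady-state summaries, half-times, plateaus, length distributions,
# closed-form oracle.

fake_traj <- function(t, n_mt, mean_length, free_conc) {
  structure(list(time = t, n_mt = n_mt, mean_length = mean_length,
                 free_conc = free_conc), class = "mt_trajectory")
}

test_that("steady-state summary averages in time then across replicates", {
  t <- 0:100
  tr1 <- fake_traj(t, rep(400, 101), rep(20, 101), rep(12, 101))
  s1 <- steady_state_summary(tr1, window = c(50, 100))
  expect_equal(s1$mean, c(400, 20, 12))
  expect_equal(s1$sd, c(0, 0, 0))

  tr2 <- fake_traj(t, rep(410, 101), rep(21, 101), rep(13, 101))
  s2 <- steady_state_summary(list(tr1, tr2), window = c(50, 100))
  expect_equal(s2$mean, c(405, 20.5, 12.5))
  expect_equal(s2$sd, c(sd(c(400, 410)), sd(c(20, 21)), sd(c(12, 13))))
  expect_equal(attr(s2, "n_replicates"), 2)

  expect_error(steady_state_summary(tr1, window = c(50, 200)), "span")
  expect_error(steady_state_summary(tr1, window = c(60, 50)))
})

test_that("plateau detection accepts stationarity and rejects ramps", {
  set.seed(7)
  noise <- rnorm(5000, mean = 100, sd = 5)
  expect_true(plateau_reached(noise, window = 1000))
  ramp <- seq(0, 100, length.out = 5000)
  expect_false(plateau_reached(ramp, window = 1000))
  expect_error(plateau_reached(1:10, window = 5), "longer")
})

test_that("half-time is the midpoint crossing, interpolated and scale-free", {
  t <- 0:2000
  expo <- 498 * exp(-t * log(2) / 200)
  expect_equal(half_time(expo, t), 200, tolerance = 1e-2)
  # linear 100 -> 0 over 400 s: the asymptote estimate is the mean of the
  # last 10% (= 5), so the midpoint 52.5 is crossed at t = 190
  lin <- seq(100, 0, length.out = 401)
  expect_equal(half_time(lin, 0:400), 190)
  # rising series work symmetrically
  expect_equal(half_time(100 - lin, 0:400), 190)
  # amplitude scaling leaves the crossing unchanged
  expect_equal(half_time(7.3 * expo, t), half_time(expo, t))
  expect_true(is.na(half_time(c(10, 9.8, 9.9, 10.1, 10), 0:4)))
  expect_true(is.na(half_time(rep(5, 10), 0:9)))
})

test_that("length histogram is right-closed, conserving, validated", {
  h <- length_histogram(c(25, 25, 24.5), bin_width = 1, max_radius = 25)
  expect_equal(unname(h[25]), 3)
  expect_equal(sum(h), 3)
  expect_true(all(length_histogram(numeric(0), 1, 25) == 0))
  expect_equal(sum(length_histogram(runif(100, 0, 25), 1, 25)), 100)
  # zero lengths are kept (first bin)
  expect_equal(sum(length_histogram(c(0, 0.5), 1, 25)), 2)
  expect_error(length_histogram(c(1, 26), 1, 25), "outside")
  expect_error(length_histogram(-0.1, 1, 25), "outside")
})

test_that("radial fractions use five fifths and sum to one", {
  set.seed(1)
  u <- radial_fraction_histogram(runif(20000, 0, 25), 25)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_true(all(abs(u - 0.2) < 0.02))
  expect_equal(unname(radial_fraction_histogram(rep(22.6, 5), 22.6)),
               c(0, 0, 0, 0, 1))
  # counting oracle: 1,2,3,4,5 lengths dropped into successive fifths
  lens <- unlist(lapply(1:5, function(k) rep(25 * (k - 0.5) / 5, k)))
  expect_equal(unname(radial_fraction_histogram(lens, 25)), (1:5) / 15)
  expect_error(radial_fraction_histogram(numeric(0), 25), "no lengths")
  expect_error(radial_fraction_histogram(26, 25), "outside")
})

test_that("bounded-regime mean length matches the closed form", {
  # NEBD dynamics at 7 uM free tubulin (v_g = 0.0167 * 7)
  expect_equal(dogterom_leibler_mean(0.1169, 0.205, 0.075, 0.023),
               1.889006, tolerance = 1e-6)
  # no-rescue limit collapses to v_g / k_c
  expect_equal(dogterom_leibler_mean(0.1, 0.2, 0.05, 0), 0.1 / 0.05)
  # Set B at 12.5 uM free is growth-biased: no stationary distribution
  expect_true(is.na(dogterom_leibler_mean(0.20875, 0.188, 0.053, 0.086)))
})

test_that("tip-length files read back and validate", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# lengths in um", "12.5", "20.25", "", "3"), f)
  expect_equal(read_tip_lengths(f), c(12.5, 20.25, 3))
  f2 <- tempfile()
  writeLines("-4", f2)
  expect_error(read_tip_lengths(f2), "non-negative")
  expect_error(read_tip_lengths("does/not/exist.txt"), "no such file")
})
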
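test_that("release-curve generator is exact at sigma = 0 and seeded", {
  rc <- noiseless_curve("gompertz", pbs_gompertz)
  expect_equal(nrow(rc), 12L)
  expect_equal(range(rc$time_h), c(0.5, 170))
  expect_equal(rc$q_pct, gompertz_q(rc$time_h, 83, 0.83, -2.7))

  # same seed reproduces bit-exactly, different seeds differ
  a <- generate_release_curve("gompertz", pbs_gompertz, sigma = 2, seed = 9)
  b <- generate_release_curve("gompertz", pbs_gompertz, sigma = 2, seed = 9)
  c <- generate_release_curve("gompertz", pbs_gompertz, sigma = 2, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$q_pct, c$q_pct))

  # zero-order with clipping off grows without bound
  z <- noiseless_curve("zero_order", c(K0 = 2),
    times = c(1, 10, 100, 1000)
  )
  expect_equal(z$q_pct, c(2, 20, 200, 2000))
  # clipping truncates to the physical window
  zc <- generate_release_curve("zero_order", c(K0 = 2),
    times = c(1, 10, 100, 1000), sigma = 0, clip = c(0, 105)
  )
  expect_equal(max(zc$q_pct), 105)
  expect_error(
    generate_release_curve("gompertz", c(Qmax = 83)), "needs parameters"
  )
})

test_that("plane-sheet series satisfies its boundary and tail behaviour", {
  D <- 1e-8
  L <- 0.01
  rc <- generate_fickian_series_curve(D, L, c(0, 0.05, 0.2, 0.5, 1, 2, 5, 20))
  expect_equal(rc$q_pct[1], 0) # series sums to 1 at t = 0
  expect_true(all(diff(rc$q_pct) > 0)) # strictly increasing
  expect_true(all(rc$q_pct >= 0 & rc$q_pct <= 100))
  # equilibrium: by tau = D t / L^2 = 10 the sheet is fully released
  t_eq <- 10 * L^2 / D / 3600
  eq <- generate_fickian_series_curve(D, L, c(t_eq, 2 * t_eq))
  expect_equal(eq$q_pct, c(100, 100), tolerance = 1e-6)
  # large-t tail matches the single-term long-time law
  t_tail <- seq(2, 6, by = 1)
  series <- generate_fickian_series_curve(D, L, t_tail)$q_pct / 100
  one_term <- 1 - (8 / pi^2) * exp(-pi^2 * D * t_tail * 3600 / (4 * L^2))
  expect_equal(series, one_term, tolerance = 1e-8)
})

test_that("surface generator hits the target Ra and is seeded", {
  p <- generate_surface_profile(117, n = 1000, seed = 4)
  expect_equal(roughness(p)$ra, 117, tolerance = 1e-6)
  p2 <- generate_surface_profile(132, n = 1000, seed = 4)
  expect_equal(roughness(p2)$ra, 132, tolerance = 1e-6)
  expect_identical(
    generate_surface_profile(117, 500, seed = 8),
    generate_surface_profile(117, 500, seed = 8)
  )
  flat <- generate_surface_profile(0, n = 50, seed = 1)
  expect_equal(roughness(flat)$ra, 0)
  expect_error(generate_surface_profile(10, n = 1), "at least 2")
})

test_that("irradiation generator reproduces the 82-to-57 endpoints", {
  b_ref <- log(57 / 82) / log(11)
  ser <- generate_irradiation_series(82, b_ref,
    times = c(0, 0.5, 1, 2, 5, 10), sigma = 0
  )
  expect_equal(ser$q24_pct[1], 82)
  expect_equal(ser$q24_pct[6], 57, tolerance = 1e-10)
  const <- generate_irradiation_series(82, 0, sigma = 0)
  expect_true(all(const$q24_pct == 82))
})

test_that("plate generator produces the designed viability effects", {
  plate <- generate_plate("querc", 0.2,
    n_wells = 6, seed = 21, noise_sd = 0.004
  )
  tab <- viability_table(plate)
  expect_equal(tab$viability_pct, 20, tolerance = 0.15)
  full <- generate_plate("blank", 1.0, n_wells = 6, seed = 22, noise_sd = 0.004)
  expect_equal(viability_table(full)$viability_pct, 100, tolerance = 0.1)
  expect_identical(
    generate_plate("g", 0.5, seed = 31), generate_plate("g", 0.5, seed = 31)
  )
  expect_error(generate_plate("g", 1.5), "\\[0, 1.2\\]")
})
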
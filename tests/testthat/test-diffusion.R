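# Times are hours; D is reported in cm^2/s (internal conversion by 3600).

test_that("short-time estimator inverts exact square-root data", {
  D <- 1e-8
  L <- 0.01
  t_h <- seq(0.01, 1, by = 0.01)
  frac <- (2 / L) * sqrt(D * t_h * 3600 / pi)
  rc <- release_curve(t_h[frac <= 0.6], 100 * frac[frac <= 0.6])
  est <- estimate_D_short(rc, L, m_inf = 100)
  expect_equal(est$D, D, tolerance = 1e-10)
  expect_equal(est$regime, "short_time")
  expect_length(est$flags, 0)
})

test_that("long-time estimator inverts exact single-exponential data", {
  D <- 1e-8
  L <- 0.01
  t_h <- seq(1, 10, by = 0.5)
  frac <- 1 - (8 / pi^2) * exp(-pi^2 * D * t_h * 3600 / (4 * L^2))
  rc <- release_curve(t_h, 100 * frac)
  est <- estimate_D_long(rc, L, m_inf = 100)
  expect_equal(est$D, D, tolerance = 1e-10)
  expect_equal(est$intercept, log(8 / pi^2), tolerance = 1e-10)
})

test_that("both regimes recover the generating D of the series solution", {
  D <- 1e-8
  L <- 0.01
  rc <- generate_fickian_series_curve(D, L, times_h = seq(0.05, 8, by = 0.05))
  ds <- estimate_D_short(rc, L, m_inf = 100)
  dl <- estimate_D_long(rc, L, m_inf = 100, floor = 0.5)
  expect_equal(ds$D, D, tolerance = 0.05)
  expect_equal(dl$D, D, tolerance = 0.05)
  # the two asymptotic estimates agree with each other within 10%
  expect_lt(abs(ds$D - dl$D) / dl$D, 0.1)
})

test_that("D scales as L^2 on the same normalized curve", {
  rc <- generate_fickian_series_curve(1e-8, 0.01, seq(0.05, 8, by = 0.05))
  for (fac in c(2, 0.5)) {
    expect_equal(
      estimate_D_short(rc, 0.01 * fac, 100)$D,
      fac^2 * estimate_D_short(rc, 0.01, 100)$D,
      tolerance = 1e-12
    )
    expect_equal(
      estimate_D_long(rc, 0.01 * fac, 100)$D,
      fac^2 * estimate_D_long(rc, 0.01, 100)$D,
      tolerance = 1e-12
    )
  }
})

test_that("estimates are invariant to joint rescaling of q and m_inf", {
  rc <- generate_fickian_series_curve(1e-8, 0.01, seq(0.05, 8, by = 0.05))
  rc2 <- release_curve(rc$time_h, rc$q_pct * 0.83)
  expect_equal(
    estimate_D_short(rc2, 0.01, m_inf = 83)$D,
    estimate_D_short(rc, 0.01, m_inf = 100)$D,
    tolerance = 1e-12
  )
  expect_equal(
    estimate_D_long(rc2, 0.01, m_inf = 83)$D,
    estimate_D_long(rc, 0.01, m_inf = 100)$D,
    tolerance = 1e-12
  )
})

test_that("regime preconditions and degenerate points are handled", {
  rc <- generate_fickian_series_curve(1e-8, 0.01, seq(1, 8, by = 0.5))
  # all points deep in the long-time regime: no short-time points left
  expect_error(
    estimate_D_short(rc, 0.01, 100, cutoff = 0.2),
    "no short-time regime"
  )
  # points clipped at Mt = Minf are dropped with a warning, estimate returned
  clipped <- release_curve(
    c(rc$time_h, 20, 25), c(rc$q_pct, 100, 100)
  )
  expect_warning(
    est <- estimate_D_long(clipped, 0.01, 100),
    "excluded"
  )
  expect_equal(est$D, 1e-8, tolerance = 0.05)
})

test_that("m_inf policies resolve as documented", {
  rc <- generate_release_curve(
    model = "gompertz", params = pbs_gompertz, sigma = 0
  )
  expect_equal(m_inf_value(rc, "gompertz")$m_inf, 83, tolerance = 1e-4)
  expect_equal(m_inf_value(rc, "last")$m_inf, gompertz_q(170, 83, 0.83, -2.7))
  expect_equal(m_inf_value(rc, "value", value = 90)$m_inf, 90)
  expect_error(m_inf_value(rc, "value"), "positive")
})
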
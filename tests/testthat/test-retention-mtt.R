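test_that("signed retention follows the uptake convention", {
  expect_equal(retention_signed(0.200, 0.314), 57)
  expect_equal(retention_signed(0.5, 0.5), 0)
  expect_equal(retention_signed(0.200, 0.170), -15)
  # literal dry-minus-wet orientation is the negation
  expect_equal(
    retention_signed(0.200, 0.314, convention = "dry_minus_wet"), -57
  )
  expect_error(retention_signed(0, 0.1), "positive")
  expect_error(retention_signed(-1, 0.1), "positive")
})

test_that("retention is antisymmetric and scale-invariant", {
  set.seed(3)
  m0 <- runif(25, 0.5, 1)
  gap <- runif(25, 0, 0.45)
  # reflecting the mass gap about meq = m0 flips the sign
  expect_equal(
    retention_signed(m0, m0 + gap), -retention_signed(m0, m0 - gap)
  )
  # joint rescaling of the two masses leaves the percent unchanged
  expect_equal(
    retention_signed(10 * m0, 10 * (m0 + gap)),
    retention_signed(m0, m0 + gap)
  )
})

test_that("contact-angle summaries flag hydrophobicity above 90 degrees", {
  s <- summarize_angles(rep(129, 5))
  expect_equal(s$mean, 129)
  expect_equal(s$sd, 0)
  expect_true(s$hydrophobic)
  one <- summarize_angles(89)
  expect_equal(one$mean, 89)
  expect_false(one$hydrophobic)
  expect_true(is.na(one$sd))
  tri <- summarize_angles(c(111, 112, 113))
  expect_equal(tri$mean, 112)
  expect_equal(tri$sd, 1)
  expect_error(summarize_angles(numeric(0)), "at least one")
  expect_error(summarize_angles(c(120, 185)), "0, 180")
})

test_that("background correction subtracts 655 nm from 595 nm", {
  expect_equal(corrected_signal(0.8, 0.1), 0.7)
  expect_equal(corrected_signal(0.42, 0), 0.42)
  expect_warning(v <- corrected_signal(0.1, 0.2), "negative")
  expect_equal(v, -0.1)
  expect_error(corrected_signal(-0.1, 0), "non-negative")
})

test_that("percent viability normalizes to the untreated mean", {
  u <- c(0.68, 0.72, 0.70)
  expect_equal(percent_viability(u, u)$viability_pct, 100)
  expect_equal(percent_viability(0.2 * u, u)$viability_pct, 20)
  expect_equal(percent_viability(rep(0, 3), u)$viability_pct, 0)
  expect_error(percent_viability(u, rep(0, 3)), "positive")
  # scale invariance: path length cancels
  t <- c(0.30, 0.33, 0.31)
  expect_equal(
    percent_viability(5 * t, 5 * u)$viability_pct,
    percent_viability(t, u)$viability_pct
  )
  expect_equal(
    percent_viability(5 * t, 5 * u)$se_pct,
    percent_viability(t, u)$se_pct
  )
})

test_that("viability_table normalizes per timepoint to the control group", {
  plate <- rbind(
    generate_plate(c("membrane", "membrane_querc"), c(1.0, 0.2),
      n_wells = 4, timepoint_h = 24, seed = 5, noise_sd = 0.005
    ),
    generate_plate(c("membrane", "membrane_querc"), c(0.95, 0.1),
      n_wells = 4, timepoint_h = 72, seed = 6, noise_sd = 0.005
    )
  )
  tab <- viability_table(plate)
  expect_equal(nrow(tab), 4L)
  v24 <- tab$viability_pct[tab$group == "membrane_querc" &
    tab$timepoint_h == 24]
  v72 <- tab$viability_pct[tab$group == "membrane_querc" &
    tab$timepoint_h == 72]
  expect_equal(v24, 20, tolerance = 0.1) # 10% relative on a ~20% signal
  expect_equal(v72, 10, tolerance = 0.2)
  expect_error(viability_table(plate, "missing_ctrl"), "absent")
})
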
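test_that("r_squared matches hand-computed values and conventions", {
  obs <- c(2, 4, 9, 11)
  expect_equal(r_squared(obs, obs), 1) # perfect fit
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0) # mean baseline
  # SSres = 200, SStot = 50 about the mean 5 => 1 - 4 = -3
  expect_equal(r_squared(c(0, 10), c(10, 0)), -3)
  expect_error(r_squared(1:3, 1:4), "equal length")
  expect_error(r_squared(c(5, 5, 5), c(1, 2, 3)), "identical")
})

test_that("r_squared is invariant under common affine rescaling", {
  set.seed(11)
  for (i in 1:20) {
    o <- rnorm(8, 50, 20)
    p <- o + rnorm(8, 0, 5)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -100, 100)
    expect_equal(r_squared(a * o + b, a * p + b), r_squared(o, p))
  }
})

test_that("noiseless model-generated data recover parameters to 1e-4", {
  cases <- list(
    list(model = "zero_order", params = c(K0 = 0.66)),
    list(model = "higuchi", params = c(KH = 9.49)),
    list(model = "korsmeyer_peppas", params = c(KR = 48.60, n = 0.13)),
    list(model = "gompertz", params = pbs_gompertz),
    list(model = "gompertz", params = ph3_gompertz)
  )
  for (cs in cases) {
    rc <- noiseless_curve(cs$model, cs$params)
    fit <- fit_release_model(rc, cs$model)
    expect_true(fit$converged)
    expect_equal(fit$params[names(cs$params)], cs$params, tolerance = 1e-4)
    expect_gt(fit$r2, 1 - 1e-8)
    # predictions regenerate bit-identically from the stored parameters
    expect_identical(predict(fit), fit$fitted)
  }
})

test_that("Monte-Carlo recovery: mean fitted beta within 10% of truth", {
  beta_hat <- vapply(1:50, function(s) {
    rc <- generate_release_curve(
      model = "gompertz", params = pbs_gompertz, sigma = 2, seed = s
    )
    fit_release_model(rc, "gompertz")$params[["beta"]]
  }, numeric(1))
  expect_equal(mean(beta_hat), -2.7, tolerance = 0.1)
})

test_that("plateauing curves give negative R2 for zero-order fits", {
  rc <- noiseless_curve("gompertz", pbs_gompertz)
  expect_lt(fit_release_model(rc, "zero_order")$r2, 0)
})

test_that("t = 0 points are excluded only where the model needs it", {
  rc <- release_curve(c(0, 1, 4, 24, 96), c(0, 36, 58, 75, 82))
  f_g <- fit_release_model(rc, "gompertz")
  expect_equal(f_g$n_excluded_t0, 1L)
  expect_equal(f_g$n_obs, 4L)
  f_z <- fit_release_model(rc, "zero_order")
  expect_equal(f_z$n_excluded_t0, 0L)
  expect_equal(f_z$n_obs, 5L)
})

test_that("degenerate and undersized inputs are rejected with diagnostics", {
  flat <- release_curve(c(1, 2, 3, 4), rep(50, 4))
  expect_error(fit_release_model(flat, "gompertz"), "degenerate")
  expect_error(fit_release_model(flat, "korsmeyer_peppas"), "degenerate")
  short <- release_curve(c(1, 2, 3), c(10, 20, 25))
  expect_error(fit_release_model(short, "gompertz"), "at least 4 points")
})

test_that("compare_models ranks the generating model first and isolates errors", {
  rc <- generate_release_curve(
    model = "gompertz", params = pbs_gompertz, sigma = 2, seed = 42
  )
  cmp <- compare_models(rc)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$table$model[1], "gompertz")
  expect_true(all(diff(cmp$table$r2[cmp$table$converged]) <= 1e-12))

  # a single-model comparison is a table of length 1
  one <- compare_models(rc, "higuchi")
  expect_equal(nrow(one$table), 1L)

  # 3 points: gompertz cannot fit, the others still do
  small <- release_curve(c(1, 4, 24), c(36, 58, 75))
  cmp3 <- compare_models(small)
  tab <- cmp3$table
  expect_false(tab$converged[tab$model == "gompertz"])
  expect_true(all(tab$converged[tab$model %in% c("zero_order", "higuchi")]))
  gfit <- cmp3$fits[[which(tab$model == "gompertz")]]
  expect_match(gfit$diagnostics, "at least")
})

test_that("comparison ranking is a pure function of r2, ties by parsimony", {
  # exact Higuchi data: higuchi and korsmeyer_peppas(n=0.5) tie at r2 = 1;
  # the one-parameter model must rank first
  rc <- noiseless_curve("higuchi", c(KH = 9.49))
  cmp <- compare_models(rc, c("korsmeyer_peppas", "higuchi"))
  expect_equal(cmp$table$r2, c(1, 1), tolerance = 1e-9)
  expect_equal(cmp$table$model[1], "higuchi")
})

test_that("comparison_report emits the long-format parameter table", {
  rc <- noiseless_curve("gompertz", pbs_gompertz)
  rep <- comparison_report(compare_models(rc))
  expect_true(all(
    c("medium", "model", "parameter", "value", "converged") %in% names(rep)
  ))
  expect_true(all(c("Qmax", "alpha", "beta", "K0", "KH", "KR", "n", "R2")
  %in% rep$parameter))
  g <- rep[rep$model == "gompertz", ]
  expect_equal(g$value[g$parameter == "Qmax"], 83, tolerance = 1e-4)
})
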
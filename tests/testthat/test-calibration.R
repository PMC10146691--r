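test_that("pointwise CF matches hand arithmetic", {
  expect_equal(cf_point(0.75, 3, 1), 1.0)
  expect_equal(cf_point(0.5, 1, 1), 1.0)
  expect_equal(cf_point(0.717, 3, 1), 3 * (1 - 0.717) / 0.717, tolerance = 1e-12)
  expect_equal(cf_point(0.717, 3, 1), 1.184, tolerance = 1e-3)
  expect_error(cf_point(1, 3, 1), "degenerate")
  expect_error(cf_point(0, 3, 1), "degenerate")
})

test_that("CF point composed with viscosity recovery is an exact inverse", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 0.15, 0.85)
    mu_t <- runif(1, 1, 5)
    qt <- runif(1, 0.3, 2); qr <- runif(1, 0.3, 2)
    cfv <- cf_point(a, mu_t, 1, qt, qr)
    mu_back <- steady_viscosity(a, Q_r = qr, Q_b = qt, mu_r = 1,
                                cf_model = cf_constant(cfv))
    expect_equal(as.numeric(mu_back), mu_t, tolerance = 1e-12)
  }
})

test_that("shipped calibrations carry the published polynomials and CF0", {
  models <- builtin_cf_models()
  expect_named(models, c("4", "10", "20"))
  m20 <- models[["20"]]
  expect_equal(m20$coefficients[6], 27.95)
  expect_equal(m20$cf0, 1.183)
  expect_equal(length(m20$coefficients) - 1, 5)
  m4 <- models[["4"]]
  expect_equal(m4$cf0, 1.637)
  expect_equal(length(m4$coefficients) - 1, 3)
  expect_equal(models[["10"]]$cf0, 1.41)
  expect_error(cf_model_for_depth(7), "no shipped")
  # printed quintic at alpha = 0.5 (hand evaluation)
  expect_equal(cf_eval(m20, 0.5), 0.9960875, tolerance = 1e-7)
})

test_that("polynomial calibration recovers its own model exactly", {
  m10 <- cf_model_for_depth(10)
  a <- seq(0.12, 0.88, length.out = 25)
  fit <- fit_cf_polynomial(a, cf_eval(m10, a), depth = 10)
  expect_equal(fit$coefficients, m10$coefficients, tolerance = 1e-10)
  # idempotence: refitting the fitted model returns the same coefficients
  refit <- fit_cf_polynomial(a, cf_eval(fit, a), depth = 10)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("noisy calibration recovers the quintic within its standard errors", {
  m20 <- std_cf()
  set.seed(42)
  a <- runif(50, 0.12, 0.88)
  cfv <- cf_eval(m20, a) + rnorm(50, 0, 0.02)
  fit <- fit_cf_polynomial(a, cfv, depth = 20)
  se <- attr(fit, "se")
  expect_true(all(abs(fit$coefficients - m20$coefficients) < 3 * se))
})

test_that("underdetermined or degenerate calibrations error", {
  expect_error(fit_cf_polynomial(c(0.3, 0.6), c(1, 1.2), degree = 2),
               "at least 3 points")
  expect_error(fit_cf_polynomial(rep(0.5, 10), rep(1, 10), degree = 2),
               "rank deficient")
  expect_error(fit_cf_polynomial(seq(0.2, 0.8, 0.1), rep(1, 7), degree = 6),
               "at most 5")
})

test_that("CF0 averaging is a weighted mean with the stated properties", {
  expect_equal(cf0_constant(cf_constant(1.7)), 1.7)
  m20 <- std_cf()
  expect_equal(cf0_constant(m20, alpha_grid = 0.5), cf_eval(m20, 0.5))
  # bounded by min/max of CF over the grid
  grid <- seq(0.1, 0.9, by = 0.01)
  cf0 <- cf0_constant(m20, grid)
  expect_gte(cf0, min(cf_eval(m20, grid)))
  expect_lte(cf0, max(cf_eval(m20, grid)))
  expect_true(cf0 > 0 && cf0 < 3)
  expect_error(cf0_constant(m20, numeric(0)), "empty")
})

test_that("CF model JSON serialization roundtrips", {
  path <- tempfile(fileext = ".json")
  m <- std_cf()
  write_cf_model(m, path)
  m2 <- read_cf_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$cf0, m$cf0)
  expect_equal(m2$range, m$range)
  unlink(path)
})
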
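test_that("characteristic coefficients match the worked-example arithmetic", {
  co <- characteristic_coefficients(demo_params())
  expect_equal(co[["a"]], 0.045 * 2.2266 * 0.0288 * 53.3 * 1398.2,
               tolerance = 1e-12)
  expect_equal(co[["b"]], 0.0288 * (53.3 + 1398.2 + 53.3 * 1.5625 * 1.183),
               tolerance = 1e-12)
  expect_equal(co[["c"]], 1.183 / 2.2266, tolerance = 1e-12)
  # hand-evaluated magnitudes
  expect_equal(unname(co), c(215.05, 44.64, 0.5313), tolerance = 1e-3)
})

test_that("coefficient scaling laws in mu_b hold", {
  p1 <- demo_params(mu_b = 2.2266)
  p2 <- demo_params(mu_b = 2 * 2.2266)
  c1 <- characteristic_coefficients(p1)
  c2 <- characteristic_coefficients(p2)
  expect_equal(c2[["a"]], 2 * c1[["a"]])
  expect_equal(c2[["b"]], c1[["b"]])
  expect_equal(c2[["c"]], c1[["c"]] / 2)
})

test_that("decay rates agree with the printed worked example and Vieta", {
  lam <- eigenvalues_forward(demo_params())
  expect_equal(lam[["lambda1"]], 0.1949, tolerance = 1e-3)
  expect_equal(lam[["lambda2"]], 0.01268, tolerance = 1e-3)
  # printed rounded values are close
  expect_equal(lam[["lambda1"]], 0.1945, tolerance = 3e-3)
  expect_equal(lam[["lambda2"]], 0.0127, tolerance = 3e-3)
})

test_that("Vieta relations hold to 1e-12 for random parameter draws", {
  set.seed(101)
  for (i in 1:25) {
    p <- draw_params()
    co <- characteristic_coefficients(p)
    lam <- eigenvalues_forward(p)
    expect_equal(lam[["lambda1"]] * lam[["lambda2"]] * co[["a"]], co[["c"]],
                 tolerance = 1e-12)
    expect_equal((lam[["lambda1"]] + lam[["lambda2"]]) * co[["a"]], co[["b"]],
                 tolerance = 1e-12)
  }
})

test_that("compliance scaling divides both decay rates by the same factor", {
  set.seed(7)
  p <- draw_params()
  k <- 3.7
  p2 <- circuit_parameters(p$geometry, p$fluids, C1 = k * p$C1, C2 = k * p$C2,
                           CF0 = p$CF0)
  expect_equal(unname(eigenvalues_forward(p2)),
               unname(eigenvalues_forward(p)) / k, tolerance = 1e-12)
})

test_that("repeated and underdamped systems are rejected or flagged", {
  expect_warning(lam <- eigenvalues_from_coefficients(1, 2, 1), "repeated")
  expect_equal(unname(lam), c(1, 1), ignore_attr = TRUE)
  expect_true(attr(lam, "repeated"))
  expect_error(eigenvalues_from_coefficients(1, 1, 1), "underdamped")
  expect_error(circuit_parameters(std_geom(), fluid_pair(1, 2),
                                  C1 = 100, C2 = 50), "C1 < C2")
})

test_that("two-exponential transient and its limits behave", {
  expect_equal(analytic_beta(0, -0.1, 1.0, 0.2, 0.01), 1.9)
  expect_equal(analytic_beta(1e6, -0.1, 1.0, 0.2, 0.01), 1)
  b <- analytic_beta(100, -0.1, 1.0, 0.1945, 0.0127)
  expect_equal(b, 1 - 0.1 * exp(-19.45) + exp(-1.27), tolerance = 1e-12)
  expect_equal(b, 1.2808, tolerance = 1e-4)
})

test_that("alpha recovery flags washed-out samples", {
  a <- alpha_from_beta(c(2, 1, 0.5))
  expect_equal(as.numeric(a), c(0.5, 0, 0))
  expect_equal(attr(a, "washed_out"), c(FALSE, TRUE, TRUE))
})

test_that("switch-off amplitudes satisfy the pressure-continuity ICs", {
  d <- turnoff_solution(2, lambdas = c(2, 1))
  expect_equal(unname(d), c(-1, 2))
  expect_equal(unname(turnoff_solution(1, lambdas = c(2, 1))), c(0, 0))
  # beta(0) = beta0 and beta'(0) = 0 for random inputs
  set.seed(11)
  for (i in 1:20) {
    l1 <- runif(1, 0.05, 1); l2 <- runif(1, 0.001, 0.9 * l1)
    b0 <- runif(1, 1, 5)
    d <- turnoff_solution(b0, lambdas = c(l1, l2))
    expect_equal(d[["d1"]] + d[["d2"]], b0 - 1, tolerance = 1e-12)
    expect_equal(d[["d1"]] * l1 + d[["d2"]] * l2, 0, tolerance = 1e-12)
  }
  expect_error(turnoff_solution(2, lambdas = c(1, 1)), "repeated")
})
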
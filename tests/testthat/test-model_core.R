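test_that("PAR is 46% of shortwave, with guarded input", {
  expect_equal(shortwave_to_par(100), 46)
  expect_equal(shortwave_to_par(0), 0)
  expect_equal(shortwave_to_par(250), 115)
  expect_error(shortwave_to_par(-1), ">= 0")
})

test_that("light response matches direct arithmetic over a parameter grid", {
  grid <- expand.grid(fopt = c(0.5, 2, 5, 10, 20),
                      alpha = c(0.01, 0.05, 0.1, 0.2),
                      par = seq(0, 400, length.out = 50))
  got <- lrf_gpp(grid$fopt, grid$alpha, grid$par)
  want <- grid$fopt * (1 - exp(-grid$alpha * grid$par / grid$fopt))
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-300)), 1e-12)
  expect_identical(lrf_gpp(10, 0.05, 0), 0)
  expect_equal(lrf_gpp(10, 0.05, 200), 10 * (1 - exp(-1)))
})

test_that("light response saturates at F_opt and starts with slope alpha", {
  expect_lt(abs(lrf_gpp(10, 0.05, 10 * 10 / 0.05) - 10) / 10, 1e-4)
  # finite-difference slope at tiny PAR equals alpha to first order
  for (fopt in c(1, 5, 20)) for (alpha in c(0.02, 0.1, 0.25)) {
    eps <- 1e-6 * fopt / alpha
    slope <- lrf_gpp(fopt, alpha, eps) / eps
    expect_lt(abs(slope - alpha) / alpha, 1e-4)
  }
})

test_that("light response is monotone in PAR, F_opt and alpha", {
  par <- seq(0, 300, by = 10)
  g <- lrf_gpp(8, 0.1, par)
  expect_true(all(diff(g) >= 0))
  fopts <- seq(1, 15, by = 0.5)
  expect_true(all(diff(lrf_gpp(fopts, 0.1, 150)) >= 0))
  alphas <- seq(0.01, 0.25, by = 0.01)
  expect_true(all(diff(lrf_gpp(8, alphas, 150)) >= 0))
})

test_that("parameter containers enforce their invariants", {
  expect_error(light_response_params(-1, 0.1), "fopt")
  expect_error(light_response_params(5, 0.3), "alpha")
  p <- light_response_params(10, 0.05)
  expect_equal(lrf_gpp(p, 200), lrf_gpp(10, 0.05, 200))
  expect_error(logistic_curve(0, 1, 0.5), "a_max")
  expect_error(logistic_curve(1, 0, 0.5), "k")
  expect_error(gaussian_curve(1, 25, 0), "b_sigma")
  expect_error(constraint_spec("t_air", "scalar", list()), "curve")
})

test_that("logistic response hits its midpoint, 90% point and asymptotes", {
  cv <- logistic_curve(8, 10, 0.5)
  expect_equal(logistic_response(cv, 0.5), 4)
  expect_equal(logistic_response(cv, 0.5 + log(9) / 10), 7.2)
  expect_lt(logistic_response(cv, -100), 1e-10)
  expect_equal(logistic_response(cv, 1e6), 8)
})

test_that("logistic and gaussian responses are reparameterization-stable", {
  # the standard form is unchanged under (k, x_mid) -> same curve object
  cv1 <- logistic_curve(3, -2, 10)
  x <- seq(-5, 25, by = 0.5)
  # decreasing logistic = mirrored increasing logistic
  cv2 <- logistic_curve(3, 2, -10)
  expect_equal(logistic_response(cv1, x), logistic_response(cv2, -x))
  gc1 <- gaussian_curve(2, 25, 5)
  gc2 <- gaussian_curve(2, -25, 5)
  expect_equal(gaussian_response(gc1, x), gaussian_response(gc2, -x))
})

test_that("gaussian response peaks at its centre with one-sigma value", {
  gc <- gaussian_curve(4, 25, 6)
  expect_equal(gaussian_response(gc, 25), 4)
  expect_equal(gaussian_response(gc, 31), 4 * exp(-0.5))
  expect_equal(gaussian_response(gc, 19), 4 * exp(-0.5))
  expect_lt(gaussian_response(gc, 200), 1e-10)
})

test_that("constraints cap scalars at one and apply ceilings", {
  expect_equal(constrain_gpp(5, scalars = list(1.3)), 5)
  expect_equal(constrain_gpp(5, scalars = list(0.5), boundaries = list(3)), 2.5)
  expect_equal(constrain_gpp(5, boundaries = list(2)), 2)
  expect_error(constrain_gpp(5, scalars = list(-0.1)), "scalars")
  expect_error(constrain_gpp(-1), "gpp_raw")
})

test_that("constrained GPP never exceeds its input (random inputs)", {
  set.seed(42)
  for (i in 1:50) {
    gpp <- runif(100, 0, 15)
    sc <- replicate(sample(0:3, 1), runif(100, 0, 2), simplify = FALSE)
    bd <- replicate(sample(0:2, 1), runif(100, 0, 20), simplify = FALSE)
    out <- constrain_gpp(gpp, sc, bd)
    expect_true(all(out <= gpp + 1e-12))
  }
})

test_that("VPD follows the Magnus curve and is floored at zero", {
  expect_equal(vpd_from_temperature_humidity(20, esat_magnus(20)), 0)
  expect_equal(vpd_from_temperature_humidity(25, 0), esat_magnus(25))
  expect_equal(round(esat_magnus(25), 2), 31.60)
  expect_equal(vpd_from_temperature_humidity(10, 100), 0)
  expect_error(vpd_from_temperature_humidity(10, -5), "vapour_pressure")
})
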
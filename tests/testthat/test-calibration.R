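test_that("quality filter keeps strictly greater flags only", {
  s <- toy_series(n = 3)
  s$quality_flag <- c(0.4, 0.5, 0.6)
  expect_equal(nrow(quality_filter(s, 0.5)), 1)
  s2 <- toy_series(n = 10, qf = 1)
  expect_equal(nrow(quality_filter(s2)), 10)
  expect_warning(out <- quality_filter(s2, 1), "removed every day")
  expect_equal(nrow(out), 0)
})

test_that("semi-monthly F_opt is the 95th percentile of daily GPP", {
  s <- toy_series(n = 20, start = "2005-06-01") # days 1..15 + 16..20
  s$gpp_obs <- 1:20
  est <- estimate_fopt_alpha(s)
  expect_equal(est$fopt[1], brute_pctl(1:15, 95))
  expect_equal(est$fopt[2], brute_pctl(16:20, 95))
})

test_that("alpha is the median low-light ratio with the exclusion cap", {
  s <- toy_series(n = 15, start = "2005-06-01", par = 10)
  s$gpp_obs <- rep(1, 15)
  s$par <- c(10, 10, 10, rep(100, 12))
  s$gpp_obs[1:3] <- c(0.2, 0.4, 3.0) # ratios 0.02, 0.04, 0.30
  est <- estimate_fopt_alpha(s)
  expect_equal(est$alpha[1], 0.04) # median over all low-light ratios
  # a semi-month whose median itself exceeds the cap is discarded
  s$gpp_obs[1:3] <- c(3, 3, 3)
  expect_true(is.na(estimate_fopt_alpha(s)$alpha[1]))
  # no low-light day at all -> alpha missing
  s$par <- rep(100, 15)
  expect_true(is.na(estimate_fopt_alpha(s)$alpha[1]))
})

test_that("GPP scalar is one for a perfectly modelled site and guarded", {
  m <- biome_model("grasslands", logistic_curve(8, 10, 0.5),
                   logistic_curve(0.1, 10, 0.5))
  s <- toy_series(n = 50, par = seq(30, 250, length.out = 50))
  s$ndvi <- seq(0.4, 0.8, length.out = 50)
  s$gpp_obs <- model_gpp(m, s, constrained = FALSE)
  expect_equal(gpp_scalar(s, m), rep(1, 50), tolerance = 1e-12)
  s$gpp_obs <- s$gpp_obs / 2
  expect_equal(gpp_scalar(s, m), rep(0.5, 50), tolerance = 1e-12)
  # near-zero modelled GPP: missing, not infinite
  s$par <- rep(1e-6, 50)
  s$gpp_obs <- rep(1, 50)
  expect_true(all(is.na(gpp_scalar(s, m))))
})

test_that("predicted alpha respects the model cap", {
  m <- biome_model("x", logistic_curve(8, 10, 0.5),
                   logistic_curve(0.4, 10, 0.5), alpha_limit = 0.08)
  pa <- predict_fopt_alpha(m, c(0.2, 0.9))
  expect_true(all(pa$alpha <= 0.08))
  m$alpha_limit <- NULL
  pa2 <- predict_fopt_alpha(m, 0.99)
  expect_true(all(pa2$alpha <= 0.25))
})

test_that("tree importance finds the driving variable and normalizes", {
  set.seed(5)
  n <- 600
  drivers <- data.frame(t_air = runif(n, 0, 30), swc = runif(n, 5, 45),
                        vpd = runif(n, 0, 40), co2 = runif(n, 380, 420))
  scal <- 1 / (1 + exp(-0.5 * (drivers$t_air - 15))) + rnorm(n, 0, 0.02)
  vi <- variable_importance(scal, drivers)
  expect_equal(names(vi)[1], "t_air")
  expect_gt(vi[["t_air"]], 0.9)
  expect_equal(sum(vi), 1)
  # scalar independent of drivers: no single driver dominates
  vi2 <- variable_importance(rnorm(n), drivers, seed = 2)
  expect_true(all(vi2 < 0.6))
  # constant scalar: zeros with warning
  expect_warning(vi3 <- variable_importance(rep(1, n), drivers), "constant")
  expect_true(all(vi3 == 0))
  expect_error(variable_importance(rnorm(50), drivers[1:50, ]), "complete")
})

test_that("constraint building keeps a real T_air effect, drops inert drivers", {
  tr <- synthetic_truth_tair_stress()
  sites <- gen_sites(tr, n_sites = 6, n_years = 3, seed = 3)
  pooled <- do.call(rbind, lapply(sites, function(s) quality_filter(s$series)))
  est <- estimate_fopt_alpha(pooled)
  cf <- lrfgpp:::fit_ndvi_curves(est, 95, 50)
  m <- biome_model(pooled$biome[1], cf$fopt$curve, cf$alpha$curve)
  scal <- gpp_scalar(pooled, m)
  vi <- variable_importance(scal, pooled[c("t_air", "swc", "vpd")])
  expect_equal(names(vi)[1], "t_air")
  m <- build_constraints(pooled, m, ranking = names(vi))
  vars <- vapply(m$constraints, function(cs) cs$variable, "")
  modes <- vapply(m$constraints, function(cs) cs$mode, "")
  expect_true("t_air" %in% vars[modes == "scalar"])
  expect_false(any(vars %in% c("swc", "vpd")))
  # the inclusion rule never increases evaluation RMSE
  dec <- attr(m, "decisions")
  expect_true(all(dec$kept %in% c(TRUE, FALSE)))
  m_bare <- biome_model(pooled$biome[1], cf$fopt$curve, cf$alpha$curve)
  expect_lte(lrfgpp:::eval_rmse(m, pooled),
             lrfgpp:::eval_rmse(m_bare, pooled))
  # scalar curves are normalized to a maximum response of one
  for (cs in m$constraints[modes == "scalar"])
    expect_lte(cs$curve$a_max, 1)
})

test_that("percentile sensitivity recovers its own refit at the argmin", {
  tr <- synthetic_truth()
  sites <- gen_sites(tr, n_sites = 4, n_years = 2, seed = 5)
  pooled <- do.call(rbind, lapply(sites, function(s) quality_filter(s$series)))
  est <- estimate_fopt_alpha(pooled)
  sens <- percentile_sensitivity(est, pooled, fopt_grid = seq(20, 100, 20),
                                 alpha_grid = seq(20, 100, 20))
  expect_equal(dim(sens$surface), c(5L, 5L))
  expect_true(is.finite(sens$surface[as.character(sens$fopt_pct),
                                     as.character(sens$alpha_pct)]))
  expect_equal(min(sens$surface, na.rm = TRUE),
               sens$surface[as.character(sens$fopt_pct),
                            as.character(sens$alpha_pct)])
  expect_s3_class(sens$fopt_curve, "logistic_curve")
})

test_that("bootstrap is seed-reproducible and evaluates withheld data only", {
  tr <- synthetic_truth()
  sites <- lapply(gen_sites(tr, n_sites = 3, n_years = 2, seed = 8),
                  function(s) quality_filter(s$series))
  tmpl <- {
    pooled <- do.call(rbind, sites)
    est <- estimate_fopt_alpha(pooled)
    cf <- lrfgpp:::fit_ndvi_curves(est, 95, 50)
    biome_model(pooled$biome[1], cf$fopt$curve, cf$alpha$curve)
  }
  b1 <- bootstrap_calibrate(sites, tmpl, n_iter = 8, seed = 99,
                            n_bins = 10, min_count = 3)
  b2 <- bootstrap_calibrate(sites, tmpl, n_iter = 8, seed = 99,
                            n_bins = 10, min_count = 3)
  expect_identical(b1$params, b2$params)
  expect_identical(b1$report, b2$report)
  # marker site: wildly biased observations blow up RMSE only when withheld
  marker <- sites[[3]]
  marker$gpp_obs <- marker$gpp_obs + 50
  sites2 <- list(sites[[1]], sites[[2]], marker)
  b3 <- bootstrap_calibrate(sites2, tmpl, n_iter = 20, seed = 7,
                            n_bins = 10, min_count = 3)
  with_marker <- grepl("(^|;)3(;|$)", b3$report$omitted)
  expect_true(any(with_marker) && any(!with_marker))
  expect_gt(min(b3$report$rmse[with_marker]), 20)
  expect_lt(min(b3$report$rmse[!with_marker]), 20)
})

test_that("single-site biomes bootstrap over site-years", {
  tr <- synthetic_truth()
  one <- quality_filter(gen_site(tr, "ONLY", n_years = 3, seed = 12)$series)
  est <- estimate_fopt_alpha(one)
  cf <- lrfgpp:::fit_ndvi_curves(est, 95, 50, n_bins = 8, min_count = 2)
  tmpl <- biome_model(one$biome[1], cf$fopt$curve, cf$alpha$curve)
  b <- bootstrap_calibrate(list(one), tmpl, n_iter = 5, seed = 2,
                           n_bins = 8, min_count = 2)
  expect_equal(nrow(b$report), 5)
  expect_true(all(is.finite(b$report$rmse)))
})
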
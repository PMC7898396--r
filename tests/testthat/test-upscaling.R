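test_that("IGBP classes merge into the eight biomes", {
  expect_equal(merge_igbp(7)[1], 6) # open shrublands -> savannah/shrublands
  expect_equal(merge_igbp(11)[1], 7) # wetlands -> grasslands
  expect_equal(merge_igbp(14)[1], 8) # mosaic -> croplands
  expect_equal(merge_igbp(16)[1], 0) # barren -> non-vegetated
  expect_equal(merge_igbp(1:5), 1:5, ignore_attr = TRUE)
  expect_error(merge_igbp(matrix(c(1, 17), 1)), "unknown IGBP")
})

test_that("fields normalize latitude and demand units", {
  v <- matrix(1:12, 3, 4)
  f <- gridded_field(v, lat = c(10, 20, 30), lon = 1:4, units = "x")
  expect_equal(f$lat, c(30, 20, 10))
  expect_equal(f$values[3, , 1], v[1, ])
  expect_error(gridded_field(v, c(10, 20, 30), 1:4, units = ""), "units")
  expect_error(gridded_field(v, c(10, 30, 20), 1:4, units = "x"),
               "monotone")
})

test_that("bilinear regridding is exact for planes and identities", {
  lat <- seq(50, 10, by = -10); lon <- seq(0, 40, by = 10)
  plane <- outer(lat, lon, function(la, lo) 2 + 0.3 * lo - 0.1 * la)
  f <- gridded_field(plane, lat, lon, units = "x")
  # identity on the same grid
  same <- regrid_bilinear(f, lat, lon)
  expect_equal(same$values, f$values, tolerance = 1e-12)
  # exact on a refined interior grid
  lat2 <- seq(45, 15, by = -5); lon2 <- seq(5, 35, by = 5)
  out <- regrid_bilinear(f, lat2, lon2)
  want <- outer(lat2, lon2, function(la, lo) 2 + 0.3 * lo - 0.1 * la)
  expect_equal(out$values[, , 1], want, tolerance = 1e-12)
  # constant stays constant
  fc <- gridded_field(matrix(7, 5, 5), lat, lon, units = "x")
  expect_true(all(regrid_bilinear(fc, lat2, lon2)$values == 7))
  # categorical maps use nearest neighbour (values stay in the code set)
  codes <- matrix(sample(c(1, 2, 3), 25, TRUE), 5, 5)
  fn <- gridded_field(codes, lat, lon, units = "code")
  nn <- regrid_bilinear(fn, lat2, lon2, method = "nearest")
  expect_true(all(nn$values %in% c(1, 2, 3)))
  expect_error(regrid_bilinear(f, c(89, 88), c(300, 301)), "overlap")
})

test_that("missing source cells propagate through regridding", {
  lat <- c(30, 20, 10); lon <- c(0, 10, 20)
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  f <- gridded_field(v, lat, lon, units = "x")
  out <- regrid_bilinear(f, c(22, 18), c(8, 12))
  expect_true(anyNA(out$values))
})

test_that("cell areas integrate to the area of the sphere", {
  lat <- seq(-89.5, 89.5, by = 1)
  lon <- seq(-179.5, 179.5, by = 1)
  total <- sum(cell_areas(lat, lon))
  expect_lt(abs(total - 4 * pi * 6371000^2) / (4 * pi * 6371000^2), 1e-6)
})

test_that("annual budget matches the closed form and is additive", {
  lat <- seq(10.5, 19.5, by = 1); lon <- seq(20.5, 29.5, by = 1)
  dates <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = "day")
  ones <- array(1, c(10, 10, 365))
  f <- gridded_field(ones, lat, lon, time = dates, units = "gC m-2 day-1")
  A <- sum(cell_areas(lat, lon))
  b <- annual_budget(f)
  expect_equal(b$gpp_pgc, 365 * A * 1e-15, tolerance = 1e-12)
  zero <- gridded_field(array(0, c(10, 10, 365)), lat, lon, dates, "x")
  expect_equal(annual_budget(zero)$gpp_pgc, 0)
  # two disjoint half-domains sum to the whole
  north <- gridded_field(ones[1:5, , ], lat[1:5], lon, dates, "x")
  south <- gridded_field(ones[6:10, , ], lat[6:10], lon, dates, "x")
  expect_equal(annual_budget(north)$gpp_pgc + annual_budget(south)$gpp_pgc,
               b$gpp_pgc, tolerance = 1e-12)
  # linearity: budget of a sum equals the sum of budgets
  f2 <- gridded_field(2 * ones, lat, lon, dates, "x")
  expect_equal(annual_budget(f2)$gpp_pgc, 2 * b$gpp_pgc, tolerance = 1e-12)
  # partial years refuse by default
  part <- gridded_field(ones[, , 1:200], lat, lon, dates[1:200], "x")
  expect_error(annual_budget(part), "partial")
  expect_equal(nrow(annual_budget(part, allow_partial = TRUE)), 1)
})

test_that("trend and detrended IAV recover line and residual structure", {
  tr <- suppressWarnings(trend(2 * (1:10) + 1, 1:10)) # exact fit warns in lm
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-12)
  expect_equal(tr$se, 0, tolerance = 1e-10)
  expect_equal(detrended_iav(2 * (1:10) + 1, 1:10), 0, tolerance = 1e-10)
  # order-free
  p <- sample(10)
  tr2 <- suppressWarnings(trend((2 * (1:10) + 1)[p], (1:10)[p]))
  expect_equal(tr2$slope, 2, tolerance = 1e-12)
  # line + alternating +-c has residual SD ~ c
  n <- 400; c0 <- 0.7
  y <- 0.3 * (1:n) + c0 * rep(c(1, -1), n / 2)
  expect_lt(abs(detrended_iav(y, 1:n) - c0) / c0, 0.05)
  # invariant to adding a constant or a ramp
  set.seed(4)
  z <- rnorm(30)
  expect_equal(detrended_iav(z), detrended_iav(z + 5 + 0.3 * (1:30)),
               tolerance = 1e-10)
})

test_that("per-pixel trends reconstruct the imposed slopes", {
  lat <- c(20, 10); lon <- c(0, 10)
  slopes <- matrix(c(0.1, -0.2, 0.3, 0), 2, 2)
  arr <- array(0, c(2, 2, 12))
  for (t in 1:12) arr[, , t] <- 5 + slopes * t
  f <- gridded_field(arr, lat, lon, units = "x")
  tf <- trend_field(f)
  expect_equal(tf$slope$values[, , 1], slopes, tolerance = 1e-10)
  expect_true(all(tf$se$values < 1e-10))
})

test_that("latitudinal profiles are area-weighted with missing rows kept", {
  lat <- c(40, 30, 20); lon <- c(0, 10)
  v <- matrix(rep(c(4, 3, 2), 2), 3, 2)
  f <- gridded_field(v, lat, lon, units = "x")
  prof <- latitudinal_profile(f)
  expect_equal(prof$mean, c(4, 3, 2))
  v2 <- v; v2[2, ] <- NA
  prof2 <- latitudinal_profile(gridded_field(v2, lat, lon, units = "x"))
  expect_true(is.na(prof2$mean[2]))
  # uniform field gives a flat profile
  fu <- gridded_field(matrix(1.5, 3, 2), lat, lon, units = "x")
  expect_true(all(latitudinal_profile(fu)$mean == 1.5))
})

test_that("gridded run equals the site-mode model cell by cell", {
  tr <- synthetic_truth()
  g <- gen_grid(tr, lat = seq(12, 14, 1), lon = seq(20, 22, 1),
                n_years = 1, seed = 6)
  m <- biome_model("savannah_shrublands",
                   tr$fopt_curve, tr$alpha_curve,
                   constraints = list(constraint_spec(
                     "t_air", "scalar", logistic_curve(1, 0.3, 10))))
  models <- list(savannah_shrublands = m)
  gpp <- run_grid(models, g$biome_map, g$ndvi, g$par, g$t_air, g$swc, g$vpd)
  # scalar-code oracle on every cell
  for (i in 1:3) for (j in 1:3) {
    if (g$biome_map[i, j] == 0) {
      expect_true(all(gpp$values[i, j, ] == 0))
      next
    }
    df <- data.frame(ndvi = g$ndvi$values[i, j, ], par = g$par$values[i, j, ],
                     t_air = g$t_air$values[i, j, ],
                     swc = g$swc$values[i, j, ], vpd = g$vpd$values[i, j, ])
    expect_equal(gpp$values[i, j, ], model_gpp(m, df), tolerance = 1e-12)
  }
  # a zero-PAR day yields zero GPP in vegetated cells
  g$par$values[, , 5] <- 0
  gpp2 <- run_grid(models, g$biome_map, g$ndvi, g$par, g$t_air, g$swc, g$vpd)
  expect_true(all(gpp2$values[, , 5] == 0))
  # an uncalibrated biome on the map fails before computing
  bad_map <- g$biome_map; bad_map[1, 1] <- 3
  expect_error(run_grid(models, bad_map, g$ndvi, g$par, g$t_air, g$swc,
                        g$vpd), "no calibrated model")
})

test_that("saturating NDVI and light approach the fitted maximum", {
  m <- biome_model("grasslands", logistic_curve(8, 10, 0.5),
                   logistic_curve(0.1, 10, 0.5))
  df <- data.frame(ndvi = 0.99, par = 5000, t_air = 20, swc = 25, vpd = 5)
  expect_gt(model_gpp(m, df), 0.98 * 8)
})
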
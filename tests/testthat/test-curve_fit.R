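test_that("percentile extraction equals the brute-force sorted oracle", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(c(1:10, 50, 1000, 10000), 1)
    x <- rnorm(n) * 10^sample(-2:2, 1)
    lev <- sample(1:100, 1)
    expect_equal(pctl(x, lev), brute_pctl(x, lev))
  }
})

test_that("binned percentiles honour bin specs and occupancy rules", {
  # constant response: every bin value is the constant, at any level
  x <- runif(500); y <- rep(3.3, 500)
  for (lev in c(10, 50, 98))
    expect_true(all(bin_percentile(x, y, lev, n_bins = 10)$value == 3.3))
  # y = x with many points: bin medians sit within half a bin width of centres
  set.seed(7)
  x <- runif(1000); y <- x
  bp <- bin_percentile(x, y, 50, n_bins = 20)
  ok <- bp$count >= 5
  expect_true(all(abs(bp$value[ok] - bp$centre[ok]) <= (bp$hi - bp$lo)[ok] / 2))
  # level 100 is the per-bin maximum
  y2 <- rnorm(1000)
  bp100 <- bin_percentile(x, y2, 100, n_bins = 5, min_count = 1)
  idx <- findInterval(x, seq(min(x), max(x), length.out = 6),
                      rightmost.closed = TRUE, all.inside = TRUE)
  expect_equal(bp100$value, as.numeric(tapply(y2, idx, max)))
  # sparse bins are missing, not zero
  bp2 <- bin_percentile(c(rep(0.1, 20), 0.9), c(rnorm(20), 5), 50,
                        n_bins = 4, min_count = 5)
  expect_true(is.na(bp2$value[4]))
  expect_false(is.na(bp2$value[1]))
  # fixed width bins anchored on multiples of the width
  bpw <- bin_percentile(seq(2, 27, by = 0.5), rnorm(51), 50, width = 5,
                        min_count = 1)
  expect_equal(bpw$lo[1], 0)
  expect_true(all(abs(diff(bpw$lo) - 5) < 1e-12))
})

test_that("logistic fit recovers noise-free generating parameters", {
  truth <- logistic_curve(7.5, 11, 0.48)
  x <- seq(0.1, 0.9, length.out = 20)
  fit <- fit_logistic(x, logistic_response(truth, x))
  expect_true(fit$converged)
  expect_lt(abs(fit$curve$a_max - 7.5) / 7.5, 1e-6)
  expect_lt(abs(fit$curve$k - 11) / 11, 1e-6)
  expect_lt(abs(fit$curve$x_mid - 0.48) / 0.48, 1e-6)
  # decreasing curves too (VPD-style)
  truth2 <- logistic_curve(3, -0.12, 30)
  x2 <- seq(0, 80, length.out = 20)
  fit2 <- fit_logistic(x2, logistic_response(truth2, x2))
  expect_lt(abs(fit2$curve$a_max - 3) / 3, 1e-6)
})

test_that("logistic a_max is stable under 5% multiplicative noise", {
  truth <- logistic_curve(8, 10, 0.5)
  x <- seq(0.1, 0.9, length.out = 20)
  base <- logistic_response(truth, x)
  set.seed(2024)
  rel_err <- replicate(100, {
    fit <- fit_logistic(x, base * (1 + rnorm(20, 0, 0.05)))
    if (fit$converged) abs(fit$curve$a_max - 8) / 8 else NA
  })
  expect_true(all(is.finite(rel_err)))
  expect_gt(mean(rel_err < 0.05), 0.9)
  expect_lt(median(rel_err), 0.03)
})

test_that("degenerate inputs give explicit failure status", {
  expect_false(fit_logistic(seq(0, 1, length.out = 10), rep(2, 10))$converged)
  expect_false(fit_logistic(c(0.1, 0.2), c(1, 2))$converged)
  expect_false(fit_gaussian(seq(0, 1, length.out = 10), rep(2, 10))$converged)
})

test_that("gaussian fit recovers noise-free parameters and symmetry", {
  truth <- gaussian_curve(6, 27, 8)
  x <- seq(5, 50, length.out = 20)
  fit <- fit_gaussian(x, gaussian_response(truth, x))
  expect_true(fit$converged)
  expect_lt(abs(fit$curve$a_max - 6) / 6, 1e-6)
  expect_lt(abs(fit$curve$b_mid - 27) / 27, 1e-6)
  expect_lt(abs(fit$curve$b_sigma - 8) / 8, 1e-6)
  # data symmetric about a centre puts b_mid at the symmetry centre
  xs <- seq(10, 40, length.out = 15)
  ys <- exp(-abs(xs - 25) / 6) # symmetric, non-gaussian shape
  fs <- fit_gaussian(xs, ys)
  expect_lt(abs(fs$curve$b_mid - 25), 0.5)
})

test_that("monotone data is flagged as wide or failed, not silently fit", {
  x <- seq(0, 10, length.out = 15)
  y <- 1 + 0.3 * x
  fit <- fit_gaussian(x, y)
  expect_true(!fit$converged || fit$flag == "wide")
})
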
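#' Percentile of a numeric vector
#'
#' Linear interpolation of the sorted sample (the standard type-7
#' definition), with `level` on the 1..100 scale used throughout the
#' calibration chain.
#'
#' @param x Numeric vector (NAs dropped).
#' @param level Percentile level in \[1, 100\].
#' @return The percentile value, or NA if `x` has no finite values.
#' @export
pctl <- function(x, level) {
  stopifnot(level >= 1, level <= 100)
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  stats::quantile(x, level / 100, type = 7, names = FALSE)
}

#' Binned percentiles of a response against a driver
#'
#' Splits the observed driver range into contiguous equal-width bins (either
#' a bin count or a bin width) and extracts a percentile of the response per
#' bin. Bins with fewer than `min_count` points are flagged missing (NA),
#' not zero. Conventional bin specs: NDVI 20 bins; air temperature 5 degC;
#' SWC 5 %Vol; CO2 5 ppm; VPD 25 hPa.
#'
#' @param x Driver values.
#' @param y Response values (same length).
#' @param level Percentile level in \[1, 100\].
#' @param n_bins Number of equal-width bins over the observed range.
#' @param width Alternatively, a fixed bin width anchored at
#'   `floor(min(x) / width) * width`.
#' @param min_count Minimum bin occupancy; default 5.
#' @return A data.frame of class `binned_percentiles` with columns `lo`,
#'   `hi`, `centre`, `count`, `value`; attribute `level`.
#' @export
bin_percentile <- function(x, y, level, n_bins = NULL, width = NULL,
                           min_count = 5) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no finite (x, y) pairs")
  if (is.null(n_bins) == is.null(width))
    stop("give exactly one of n_bins or width")
  if (!is.null(width)) {
    lo0 <- floor(min(x) / width) * width
    edges <- seq(lo0, max(x) + width, by = width)
  } else {
    edges <- seq(min(x), max(x), length.out = n_bins + 1)
    if (edges[1] == edges[length(edges)])
      edges <- edges + c(-0.5, seq_len(n_bins - 1) * 0, 0.5) # degenerate range
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1
  count <- tabulate(idx, nbins = nb)
  value <- rep(NA_real_, nb)
  for (b in which(count >= min_count)) value[b] <- pctl(y[idx == b], level)
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1],
                    centre = (edges[-length(edges)] + edges[-1]) / 2,
                    count = count, value = value)
  attr(out, "level") <- level
  class(out) <- c("binned_percentiles", "data.frame")
  out
}

xy_from_input <- function(x, y) {
  if (is.data.frame(x)) {
    stopifnot(all(c("centre", "value") %in% names(x)))
    y <- x$value; x <- x$centre
  }
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok])
}

nls_best <- function(formula, data, starts, lower, upper) {
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  best
}

fit_failure <- function(msg) {
  list(curve = NULL, rmse = NA_real_, converged = FALSE, flag = msg)
}

#' Fit a three-parameter logistic curve to binned percentiles
#'
#' Nonlinear least squares (Levenberg-Marquardt) with moment-based starting
#' values and a deterministic grid of perturbed restarts; the best residual
#' sum of squares wins. `a_max` is bounded in (0, 3 max(y)]. Constant data
#' is unidentifiable and returns a failure status rather than a flat curve.
#'
#' @param x Bin centres, or a `binned_percentiles` data.frame (then `y` is
#'   ignored).
#' @param y Bin percentile values.
#' @return A list with `curve` (a [logistic_curve()] or NULL), `rmse`
#'   (residual RMSE), `converged` (logical) and `flag` (diagnostic string).
#' @export
fit_logistic <- function(x, y = NULL) {
  d <- xy_from_input(x, y)
  x <- d$x; y <- d$y
  if (length(x) < 4) return(fit_failure("fewer than 4 bins"))
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    return(fit_failure("constant data: flat curve unidentifiable"))
  if (max(y) <= 0) return(fit_failure("nonpositive response"))
  a0 <- 1.05 * max(y)
  rngx <- diff(range(x))
  if (rngx == 0) return(fit_failure("degenerate x range"))
  # moment start: linearize via logit of y / a0
  z <- pmin(pmax(y / a0, 0.02), 0.98)
  lf <- stats::lm(stats::qlogis(z) ~ x)
  k0 <- unname(stats::coef(lf)[2])
  if (!is.finite(k0) || k0 == 0) k0 <- sign(stats::cor(x, y)) * 4 / rngx
  x0 <- -unname(stats::coef(lf)[1]) / k0
  if (!is.finite(x0)) x0 <- stats::median(x)
  starts <- list(list(a_max = a0, k = k0, x_mid = x0))
  for (fk in c(0.3, 3)) for (dx in c(-0.25, 0.25) * rngx) {
    starts <- c(starts, list(list(a_max = a0, k = k0 * fk, x_mid = x0 + dx)))
  }
  starts <- c(starts,
              list(list(a_max = max(y), k = 4 / rngx, x_mid = stats::median(x)),
                   list(a_max = max(y), k = -4 / rngx, x_mid = stats::median(x))))
  fit <- nls_best(y ~ a_max / (1 + exp(-k * (x - x_mid))),
                  data = data.frame(x = x, y = y), starts,
                  lower = c(a_max = 1e-8, k = -1e4, x_mid = min(x) - 5 * rngx),
                  upper = c(a_max = 3 * max(y), k = 1e4, x_mid = max(x) + 5 * rngx))
  if (is.null(fit)) return(fit_failure("nonlinear fit did not converge"))
  p <- stats::coef(fit)
  if (p[["k"]] == 0) return(fit_failure("degenerate steepness"))
  list(curve = logistic_curve(p[["a_max"]], p[["k"]], p[["x_mid"]]),
       rmse = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE,
       flag = "ok")
}

#' Fit a Gaussian (bell-shaped) curve to binned percentiles
#'
#' As [fit_logistic()] but for the Gaussian response used by the
#' soil-water-content constraint. Monotone data pushes the width toward the
#' bound and is flagged `"wide"`.
#'
#' @inheritParams fit_logistic
#' @return A list with `curve` (a [gaussian_curve()] or NULL), `rmse`,
#'   `converged` and `flag` (`"ok"`, `"wide"` or a failure message).
#' @export
fit_gaussian <- function(x, y = NULL) {
  d <- xy_from_input(x, y)
  x <- d$x; y <- d$y
  if (length(x) < 4) return(fit_failure("fewer than 4 bins"))
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    return(fit_failure("constant data: flat curve unidentifiable"))
  if (max(y) <= 0) return(fit_failure("nonpositive response"))
  rngx <- diff(range(x))
  if (rngx == 0) return(fit_failure("degenerate x range"))
  a0 <- max(y)
  b0 <- x[which.max(y)]
  yw <- pmax(y, 0)
  s0 <- sqrt(sum(yw * (x - b0)^2) / sum(yw))
  if (!is.finite(s0) || s0 <= 0) s0 <- rngx / 4
  starts <- list(list(a_max = a0, b_mid = b0, b_sigma = s0))
  for (fs in c(0.3, 3)) for (db in c(-0.25, 0, 0.25) * rngx) {
    starts <- c(starts,
                list(list(a_max = a0, b_mid = b0 + db, b_sigma = s0 * fs)))
  }
  fit <- nls_best(y ~ a_max * exp(-(x - b_mid)^2 / (2 * b_sigma^2)),
                  data = data.frame(x = x, y = y), starts,
                  lower = c(a_max = 1e-8, b_mid = min(x) - 5 * rngx,
                            b_sigma = 1e-6),
                  upper = c(a_max = 3 * max(y), b_mid = max(x) + 5 * rngx,
                            b_sigma = 10 * rngx))
  if (is.null(fit)) return(fit_failure("nonlinear fit did not converge"))
  p <- stats::coef(fit)
  # a very wide curve, or a peak outside the data, signals monotone input
  flag <- if (p[["b_sigma"]] > 3 * rngx ||
              p[["b_mid"]] < min(x) - 0.1 * rngx ||
              p[["b_mid"]] > max(x) + 0.1 * rngx) "wide" else "ok"
  list(curve = gaussian_curve(p[["a_max"]], p[["b_mid"]], p[["b_sigma"]]),
       rmse = sqrt(mean(stats::residuals(fit)^2)), converged = TRUE,
       flag = flag)
}
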
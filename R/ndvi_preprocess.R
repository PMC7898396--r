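#' Semi-monthly period of a date
#'
#' Composites follow the semi-monthly convention: day 1-15 is the first half
#' of a month, day 16 to month end the second, giving 24 composites per year.
#'
#' @param dates A `Date` vector.
#' @return A data.frame with columns `year`, `month`, `half` (1 or 2) and
#'   `sm` (composite index within the year, 1..24).
#' @export
semimonth_of <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  month <- lt$mon + 1L
  half <- ifelse(lt$mday <= 15L, 1L, 2L)
  data.frame(year = year, month = month, half = half,
             sm = (month - 1L) * 2L + half)
}

#' Construct a semi-monthly NDVI series
#'
#' @param year,month,half Period identifiers (day 1-15 vs 16-end).
#' @param ndvi NDVI values in \[-0.2, 1\]; NA marks missing composites.
#' @return A data.frame of class `ndvi_series`, ordered in time.
#' @export
ndvi_series <- function(year, month, half, ndvi) {
  stopifnot(length(year) == length(ndvi), length(month) == length(ndvi),
            length(half) == length(ndvi))
  if (any(ndvi < -0.2 | ndvi > 1, na.rm = TRUE))
    stop("ndvi outside [-0.2, 1]")
  out <- data.frame(year = as.integer(year), month = as.integer(month),
                    half = as.integer(half), ndvi = as.numeric(ndvi))
  out <- out[order(out$year, out$month, out$half), ]
  rownames(out) <- NULL
  class(out) <- c("ndvi_series", "data.frame")
  out
}

#' Median spike filter for NDVI series
#'
#' A composite is flagged missing when it deviates from the running median
#' (window 5) by more than `spike_param` times the standard deviation of the
#' series. All other values are left unchanged.
#'
#' @param series An `ndvi_series` (or numeric vector).
#' @param spike_param Deviation multiplier; default 2.
#' @param window Running-median window; default 5 (odd).
#' @return Filtered series of the same form, spikes set to NA.
#' @export
spike_filter <- function(series, spike_param = 2, window = 5) {
  stopifnot(spike_param > 0, window %% 2 == 1)
  vec_in <- is.numeric(series)
  x <- if (vec_in) series else series$ndvi
  if (length(x) < window) {
    warning("series shorter than filter window; returned unchanged")
    return(series)
  }
  # running median on a gap-interpolated copy so isolated NAs do not mask spikes
  xi <- x
  if (anyNA(xi) && sum(!is.na(xi)) >= 2) {
    xi <- stats::approx(seq_along(x), x, xout = seq_along(x), rule = 2)$y
  }
  med <- stats::runmed(xi, window, endrule = "median")
  thr <- spike_param * stats::sd(x, na.rm = TRUE)
  bad <- !is.na(x) & abs(x - med) > thr
  x[bad] <- NA
  if (vec_in) return(x)
  series$ndvi <- x
  series
}

double_logistic_fun <- function(t, p) {
  p[["base"]] + p[["amp"]] * (1 / (1 + exp(-p[["r1"]] * (t - p[["s1"]]))) -
                              1 / (1 + exp(-p[["r2"]] * (t - p[["s2"]]))))
}

running_mean_na <- function(x, window = 5, w = NULL) {
  n <- length(x)
  if (is.null(w)) w <- rep(1, n)
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    ok <- !is.na(x[j])
    out[i] <- if (any(ok)) sum(w[j][ok] * x[j][ok]) / sum(w[j][ok]) else NA_real_
  }
  out
}

fit_double_logistic_season <- function(t, y, w, envelope_iterations,
                                       adaptation_strength) {
  ok <- !is.na(y)
  if (sum(ok) < 8 || stats::sd(y[ok]) < 1e-8) return(NULL)
  base0 <- stats::quantile(y[ok], 0.05, names = FALSE)
  amp0 <- max(y[ok]) - base0
  if (amp0 < 1e-6) return(NULL)
  peak <- t[ok][which.max(y[ok])]
  start <- list(base = base0, amp = amp0, r1 = 1, s1 = peak - 4,
                r2 = 1, s2 = peak + 4)
  dat <- data.frame(t = t[ok], y = y[ok])
  wts <- w[ok]
  fit <- NULL
  for (iter in 0:envelope_iterations) {
    fit_try <- tryCatch(
      minpack.lm::nlsLM(
        y ~ base + amp * (1 / (1 + exp(-r1 * (t - s1))) -
                          1 / (1 + exp(-r2 * (t - s2)))),
        data = dat, start = start, weights = wts,
        lower = c(base = -0.2, amp = 1e-4, r1 = 0.05, s1 = min(t) - 6,
                  r2 = 0.05, s2 = min(t) - 6),
        upper = c(base = 1, amp = 1.5, r1 = 20, s1 = max(t) + 6,
                  r2 = 20, s2 = max(t) + 6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit_try)) break
    fit <- fit_try
    start <- as.list(stats::coef(fit))
    if (iter < envelope_iterations) {
      # bias toward the upper envelope: down-weight points below the curve
      resid <- dat$y - stats::predict(fit)
      wts[resid < 0] <- wts[resid < 0] / adaptation_strength
    }
  }
  fit
}

#' Double-logistic seasonal smoothing with upper-envelope iteration
#'
#' Per season (calendar year), fits the sum of two logistic transitions
#' (green-up and senescence; six parameters: base level, amplitude, two
#' inflection times and two rates) by least squares. After each fit, points
#' falling below the curve are down-weighted (weight divided by
#' `adaptation_strength`) and the fit repeated, which biases the curve
#' toward the upper envelope of the data: negatively biased composites
#' (cloud or snow contamination) are thereby suppressed. Seasons that fail
#' to converge fall back to a weighted running mean and are flagged.
#'
#' `seasonal_parameter` and `sg_window` are accepted for interface
#' compatibility with TIMESAT-style configuration but are not used by this
#' simplified smoother (the Savitzky-Golay window belongs to a different
#' smoothing method).
#'
#' @param series An `ndvi_series`.
#' @param envelope_iterations Number of envelope refits; default 2.
#' @param adaptation_strength Weight divisor per iteration; default 2.
#' @param seasonal_parameter Accepted, unused (see Details).
#' @param sg_window Accepted, unused.
#' @return The series with columns `ndvi` (smoothed, gap-filled inside the
#'   observed span) and `smooth_method` (`"double_logistic"` or
#'   `"running_mean"` per year).
#' @export
double_logistic_smooth <- function(series, envelope_iterations = 2,
                                   adaptation_strength = 2,
                                   seasonal_parameter = 0.5, sg_window = 4) {
  stopifnot(inherits(series, "ndvi_series"))
  out <- series
  out$smooth_method <- NA_character_
  for (yr in unique(series$year)) {
    sel <- which(series$year == yr)
    t <- (series$month[sel] - 1) * 2 + series$half[sel]
    y <- series$ndvi[sel]
    w <- rep(1, length(y))
    fit <- fit_double_logistic_season(t, y, w, envelope_iterations,
                                      adaptation_strength)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      out$ndvi[sel] <- double_logistic_fun(t, as.list(p))
      out$smooth_method[sel] <- "double_logistic"
    } else {
      out$ndvi[sel] <- running_mean_na(y, window = 5)
      out$smooth_method[sel] <- "running_mean"
    }
  }
  # clamp to the data range with a small margin
  rng <- range(series$ndvi, na.rm = TRUE)
  out$ndvi <- pmin(pmax(out$ndvi, rng[1] - 0.05), rng[2] + 0.05)
  out
}

#' Expand a semi-monthly NDVI series to daily resolution
#'
#' Piecewise-constant expansion: each day takes the composite value of the
#' semi-month it falls in.
#'
#' @param series An `ndvi_series` (ideally smoothed, no gaps).
#' @return A data.frame with columns `date` and `ndvi` covering every day of
#'   the series' span.
#' @export
ndvi_to_daily <- function(series) {
  stopifnot(inherits(series, "ndvi_series"))
  first <- as.Date(sprintf("%04d-%02d-%02d", series$year[1], series$month[1],
                           if (series$half[1] == 1) 1L else 16L))
  n <- nrow(series)
  last_per <- series[n, ]
  last <- if (last_per$half == 1) {
    as.Date(sprintf("%04d-%02d-15", last_per$year, last_per$month))
  } else {
    # month end
    seq(as.Date(sprintf("%04d-%02d-01", last_per$year, last_per$month)),
        by = "month", length.out = 2)[2] - 1
  }
  dates <- seq(first, last, by = "day")
  sm <- semimonth_of(dates)
  key <- paste(sm$year, sm$month, sm$half)
  skey <- paste(series$year, series$month, series$half)
  idx <- match(key, skey)
  data.frame(date = dates, ndvi = series$ndvi[idx])
}
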
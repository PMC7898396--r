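#' Validate a daily site series
#'
#' The per-site daily table used throughout calibration. Required columns:
#' `site_id`, `biome`, `date` (Date), `gpp_obs` (g C m-2 day-1),
#' `quality_flag` (0..1), `par` (W m-2), `t_air` (degC), `swc` (%Vol),
#' `vpd` (hPa), `co2` (ppm). A daily `ndvi` column (from
#' [ndvi_to_daily()]) is attached before modelling.
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame, ordered by site and date, with class
#'   `site_daily_series`.
#' @export
site_daily_series <- function(df) {
  req <- c("site_id", "biome", "date", "gpp_obs", "quality_flag", "par",
           "t_air", "swc", "vpd", "co2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!inherits(df$date, "Date")) stop("date must be a Date column")
  if (any(df$quality_flag < 0 | df$quality_flag > 1, na.rm = TRUE))
    stop("quality_flag outside [0, 1]")
  if (any(df$par < 0, na.rm = TRUE)) stop("par must be >= 0")
  df <- df[order(df$site_id, df$date), ]
  rownames(df) <- NULL
  if (!inherits(df, "site_daily_series"))
    class(df) <- c("site_daily_series", class(df))
  df
}

#' Quality-filter a daily site series
#'
#' Retains only days whose quality flag is strictly greater than the
#' threshold; all other fields are untouched.
#'
#' @param series A `site_daily_series` (or compatible data.frame).
#' @param threshold Quality threshold in \[0, 1\]; default 0.5.
#' @return The filtered series.
#' @export
quality_filter <- function(series, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- series[!is.na(series$quality_flag) & series$quality_flag > threshold, ]
  if (nrow(out) == 0) warning("quality filter removed every day")
  rownames(out) <- NULL
  out
}

#' Attach daily NDVI to a site series
#'
#' @param series A `site_daily_series`.
#' @param ndvi_daily A data.frame with `date` and `ndvi` (e.g. from
#'   [ndvi_to_daily()]).
#' @return The series with an `ndvi` column.
#' @export
attach_ndvi <- function(series, ndvi_daily) {
  series$ndvi <- ndvi_daily$ndvi[match(series$date, ndvi_daily$date)]
  series
}

#' Semi-monthly photosynthetic capacity and quantum efficiency estimates
#'
#' For each site and semi-month with data, extracts `fopt` as the
#' `fopt_level`-th percentile (default 95) of daily observed GPP and
#' `alpha` as the median of daily GPP/PAR ratios over low-light days (mean
#' daily PAR below `low_light_par`, default 25 W m-2); `alpha` is missing
#' when the semi-month has no such days, and semi-monthly estimates above
#' `alpha_cap` (default 0.25, unrealistically high) are discarded.
#'
#' @param series A quality-filtered `site_daily_series` (daily `ndvi`
#'   column optional but required downstream).
#' @param fopt_level Percentile of daily GPP used for `fopt`; default 95.
#' @param low_light_par Low-light PAR threshold, W m-2; default 25.
#' @param alpha_cap Exclusion cap on semi-monthly alpha; default 0.25.
#' @return A data.frame with one row per site semi-month: `site_id`,
#'   `year`, `month`, `half`, `n_days`, `fopt`, `alpha`, `ndvi` (semi-month
#'   mean of daily NDVI, NA if absent).
#' @export
estimate_fopt_alpha <- function(series, fopt_level = 95, low_light_par = 25,
                                alpha_cap = 0.25) {
  sm <- semimonth_of(series$date)
  key <- interaction(series$site_id, sm$year, sm$month, sm$half, drop = TRUE)
  has_ndvi <- "ndvi" %in% names(series)
  rows <- lapply(split(seq_len(nrow(series)), key), function(i) {
    g <- series$gpp_obs[i]
    ok <- is.finite(g)
    if (!any(ok)) return(NULL)
    low <- ok & is.finite(series$par[i]) & series$par[i] < low_light_par &
      series$par[i] > 0
    alpha <- if (any(low)) {
      stats::median(series$gpp_obs[i][low] / series$par[i][low])
    } else NA_real_
    if (is.finite(alpha) && alpha > alpha_cap) alpha <- NA_real_
    data.frame(site_id = series$site_id[i][1], year = sm$year[i][1],
               month = sm$month[i][1], half = sm$half[i][1],
               n_days = sum(ok), fopt = pctl(g[ok], fopt_level),
               alpha = alpha,
               ndvi = if (has_ndvi) mean(series$ndvi[i], na.rm = TRUE)
                      else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site_id, out$year, out$month, out$half), ]
}

#' Calibrated model for one biome
#'
#' Bundles the NDVI couplings (logistic curves for F_opt and alpha), an
#' optional alpha cap (the maximum binned alpha, used where sparse alpha
#' estimates make the fitted curve explode at high NDVI), the environmental
#' constraint set, the selected percentiles and bootstrap parameter
#' uncertainties.
#'
#' @param biome Biome name.
#' @param fopt_curve,alpha_curve `logistic_curve`s against NDVI.
#' @param alpha_limit Optional numeric cap on predicted alpha.
#' @param constraints List of [constraint_spec()]s (at most one per
#'   variable and mode).
#' @param selected_percentiles List with `fopt`, `alpha` and `scalars`
#'   (named per variable).
#' @param uncertainty Optional named numeric vector of bootstrap parameter
#'   standard deviations.
#' @return An object of class `biome_model`.
#' @export
biome_model <- function(biome, fopt_curve, alpha_curve, alpha_limit = NULL,
                        constraints = list(),
                        selected_percentiles = list(fopt = 95, alpha = 50,
                                                    scalars = list()),
                        uncertainty = NULL) {
  stopifnot(inherits(fopt_curve, "logistic_curve"),
            inherits(alpha_curve, "logistic_curve"))
  key <- vapply(constraints, function(cs) paste(cs$variable, cs$mode), "")
  if (anyDuplicated(key))
    stop("duplicate constraint for the same variable and mode")
  structure(list(biome = biome, fopt_curve = fopt_curve,
                 alpha_curve = alpha_curve, alpha_limit = alpha_limit,
                 constraints = constraints,
                 selected_percentiles = selected_percentiles,
                 uncertainty = uncertainty),
            class = "biome_model")
}

#' Predict F_opt and alpha from NDVI
#'
#' Evaluates the biome's logistic couplings; predicted alpha is capped at
#' the model's `alpha_limit` (when set) and at the physical cap 0.25.
#'
#' @param model A `biome_model`.
#' @param ndvi NDVI values.
#' @return A list with vectors `fopt` and `alpha`.
#' @export
predict_fopt_alpha <- function(model, ndvi) {
  fopt <- logistic_response(model$fopt_curve, ndvi)
  alpha <- logistic_response(model$alpha_curve, ndvi)
  if (!is.null(model$alpha_limit)) alpha <- pmin(alpha, model$alpha_limit)
  alpha <- pmin(alpha, 0.25)
  list(fopt = fopt, alpha = alpha)
}

constraint_values <- function(model, series) {
  scalars <- list(); boundaries <- list()
  for (cs in model$constraints) {
    v <- series[[cs$variable]]
    r <- curve_response(cs$curve, v)
    if (cs$mode == "scalar") scalars <- c(scalars, list(pmin(r, 1)))
    else boundaries <- c(boundaries, list(r))
  }
  list(scalars = scalars, boundaries = boundaries)
}

#' Model daily GPP for a site series
#'
#' The forward model: F_opt and alpha from NDVI, GPP from the asymptotic
#' light response, then (optionally) the biome's environmental scalars and
#' upper boundaries.
#'
#' @param model A `biome_model`.
#' @param series A `site_daily_series` with an `ndvi` column.
#' @param constrained Apply the constraint set? Default TRUE.
#' @return Daily modelled GPP, g C m-2 day-1.
#' @export
model_gpp <- function(model, series, constrained = TRUE) {
  if (!"ndvi" %in% names(series)) stop("series lacks an ndvi column")
  pa <- predict_fopt_alpha(model, series$ndvi)
  gpp <- lrf_gpp(pa$fopt, pa$alpha, series$par)
  if (constrained && length(model$constraints)) {
    cv <- constraint_values(model, series)
    gpp <- constrain_gpp(gpp, cv$scalars, cv$boundaries)
  }
  gpp
}

#' Daily GPP scalar: observed over NDVI/PAR-modelled GPP
#'
#' Isolates short-term meteorological and hydrological effects that the
#' NDVI-coupled light response does not capture. Undefined (missing) when
#' modelled GPP is below `eps`, guarding the division.
#'
#' @param series A `site_daily_series` with `ndvi`.
#' @param model A `biome_model` (only its NDVI curves are used).
#' @param eps Minimum modelled GPP for a defined ratio; default 0.1
#'   g C m-2 day-1.
#' @return Daily scalar values (NA where undefined).
#' @export
gpp_scalar <- function(series, model, eps = 0.1) {
  mod <- model_gpp(model, series, constrained = FALSE)
  out <- ifelse(is.finite(mod) & mod >= eps, series$gpp_obs / mod, NA_real_)
  out
}

#' Regression-tree variable importance for the GPP scalar
#'
#' Fits a binary regression tree (variance-reduction splitting) of the
#' daily GPP scalar on the meteorological and hydrological drivers and
#' reports each driver's summed impurity decrease, normalized to 1.
#' Deterministic given the seed (cross-validation is disabled).
#'
#' @param scalars Daily GPP scalar values.
#' @param drivers A data.frame of daily driver values (e.g. `t_air`,
#'   `swc`, `vpd`, `co2`).
#' @param max_depth,min_leaf,cp Tree controls; defaults 4, 20, 1e-4.
#' @param seed RNG seed; default 1.
#' @param min_days Minimum complete days required; default 100.
#' @return A named numeric vector of importances summing to 1 (or all zero,
#'   with a warning, for a constant scalar), sorted decreasing.
#' @export
variable_importance <- function(scalars, drivers, max_depth = 4,
                                min_leaf = 20, cp = 1e-4, seed = 1,
                                min_days = 100) {
  stopifnot(is.data.frame(drivers), nrow(drivers) == length(scalars))
  dat <- cbind(data.frame(.scalar = scalars), drivers)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < min_days) stop("fewer than ", min_days, " complete days")
  zero <- stats::setNames(rep(0, ncol(drivers)), names(drivers))
  if (stats::sd(dat$.scalar) < 1e-12) {
    warning("constant scalar: importances undefined, returning zeros")
    return(zero)
  }
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  fit <- rpart::rpart(.scalar ~ ., data = dat, method = "anova",
                      control = rpart::rpart.control(maxdepth = max_depth,
                                                     minbucket = min_leaf,
                                                     cp = cp, xval = 0,
                                                     maxsurrogate = 0))
  vi <- fit$variable.importance
  if (is.null(vi) || sum(vi) <= 0) {
    warning("tree made no splits: importances undefined, returning zeros")
    return(zero)
  }
  out <- zero
  out[names(vi)] <- vi / sum(vi)
  sort(out, decreasing = TRUE)
}

default_bin_width <- function(variable) {
  switch(variable, t_air = 5, swc = 5, vpd = 25, co2 = 5,
         stop("no default bin width for ", variable))
}

constraint_family <- function(variable) {
  switch(variable, t_air = "logistic", vpd = "logistic", co2 = "logistic",
         swc = "gaussian", stop("unknown constraint variable ", variable))
}

fit_constraint_curve <- function(driver, response, variable, level,
                                 min_count = 5) {
  bp <- bin_percentile(driver, response, level = level,
                       width = default_bin_width(variable),
                       min_count = min_count)
  if (sum(is.finite(bp$value)) < 4) return(NULL)
  fam <- constraint_family(variable)
  fit <- if (fam == "logistic") fit_logistic(bp) else fit_gaussian(bp)
  if (!fit$converged) return(NULL)
  fit$curve
}

normalize_scalar_curve <- function(curve) {
  # a scalar can only decrease GPP: cap the curve maximum at one
  if (curve$a_max > 1) curve$a_max <- 1
  curve
}

eval_rmse <- function(model, series) {
  mod <- model_gpp(model, series)
  ok <- is.finite(mod) & is.finite(series$gpp_obs)
  sqrt(mean((mod[ok] - series$gpp_obs[ok])^2))
}

with_constraint <- function(model, cs) {
  model$constraints <- c(model$constraints, list(cs))
  model
}

#' Build the environmental constraint set for a biome
#'
#' Walks the drivers in variable-importance order. For each driver it fits
#' a candidate scalar curve to the binned 50th-percentile GPP scalar
#' (logistic for air temperature and VPD, Gaussian for SWC) and a candidate
#' upper-boundary curve to the binned 98th-percentile observed GPP (same
#' family). A candidate enters the model only if it reduces the evaluation
#' RMSE of constrained GPP; drivers whose variability is already captured
#' by the NDVI coupling are thereby rejected. Scalar curves are normalized
#' so their maximum response does not exceed one. The CO2 constraint is
#' implemented but disabled by default.
#'
#' When `scalar_grid` has several levels, the scalar percentile is chosen
#' by a 1-D RMSE search (ties broken toward the lowest percentile).
#'
#' @param series Pooled calibration `site_daily_series` with `ndvi`.
#' @param model A `biome_model` with fitted NDVI curves (constraints are
#'   replaced).
#' @param ranking Driver names in importance order; default
#'   `c("t_air", "swc", "vpd")`.
#' @param scalar_grid Percentile level(s) for the scalar response; default
#'   50.
#' @param boundary_level Percentile for the upper boundary; default 98.
#' @param min_count Minimum bin occupancy; default 5.
#' @param eps Epsilon for the GPP scalar; default 0.1.
#' @return The model with its `constraints` list and
#'   `selected_percentiles$scalars` filled, plus an attribute `"decisions"`
#'   (a data.frame logging each candidate and whether it was retained).
#' @export
build_constraints <- function(series, model,
                              ranking = c("t_air", "swc", "vpd"),
                              scalar_grid = 50, boundary_level = 98,
                              min_count = 5, eps = 0.1) {
  model$constraints <- list()
  scal <- gpp_scalar(series, model, eps = eps)
  decisions <- list()
  base_rmse <- eval_rmse(model, series)
  for (v in ranking) {
    driver <- series[[v]]
    # scalar candidate (with optional percentile search)
    best <- NULL
    for (lev in sort(scalar_grid)) {
      curve <- fit_constraint_curve(driver, scal, v, lev, min_count)
      if (is.null(curve)) next
      cs <- constraint_spec(v, "scalar", normalize_scalar_curve(curve))
      rmse <- eval_rmse(with_constraint(model, cs), series)
      if (is.null(best) || rmse < best$rmse) best <- list(cs = cs, rmse = rmse,
                                                          level = lev)
    }
    if (!is.null(best) && best$rmse < base_rmse) {
      model <- with_constraint(model, best$cs)
      model$selected_percentiles$scalars[[v]] <- best$level
      base_rmse <- best$rmse
      kept_s <- TRUE
    } else kept_s <- FALSE
    decisions <- c(decisions, list(data.frame(
      variable = v, mode = "scalar",
      rmse = if (is.null(best)) NA_real_ else best$rmse, kept = kept_s)))
    # upper-boundary candidate on observed GPP
    curve <- fit_constraint_curve(driver, series$gpp_obs, v, boundary_level,
                                  min_count)
    kept_b <- FALSE
    rmse_b <- NA_real_
    if (!is.null(curve)) {
      cs <- constraint_spec(v, "upper_boundary", curve)
      rmse_b <- eval_rmse(with_constraint(model, cs), series)
      if (rmse_b < base_rmse) {
        model <- with_constraint(model, cs)
        base_rmse <- rmse_b
        kept_b <- TRUE
      }
    }
    decisions <- c(decisions, list(data.frame(
      variable = v, mode = "upper_boundary", rmse = rmse_b, kept = kept_b)))
  }
  attr(model, "decisions") <- do.call(rbind, decisions)
  model
}

fit_ndvi_curves <- function(estimates, fopt_pct, alpha_pct, n_bins = 20,
                            min_count = 5) {
  bp_f <- bin_percentile(estimates$ndvi, estimates$fopt, level = fopt_pct,
                         n_bins = n_bins, min_count = min_count)
  bp_a <- bin_percentile(estimates$ndvi, estimates$alpha, level = alpha_pct,
                         n_bins = n_bins, min_count = min_count)
  list(fopt = fit_logistic(bp_f), alpha = fit_logistic(bp_a),
       max_binned_alpha = suppressWarnings(max(bp_a$value, na.rm = TRUE)))
}

#' Percentile sensitivity search for the NDVI couplings
#'
#' For every pair on the (F_opt percentile, alpha percentile) grid, refits
#' the two NDVI logistic couplings with those bin-level percentiles, models
#' daily GPP (unconstrained) and computes the evaluation RMSE against
#' observations. Returns the full RMSE surface and the arg-min pair, with
#' ties broken toward the lowest percentile indices (conservative GPP).
#' The two curve fits are independent of the partner percentile, so the
#' grid costs one fit per grid line, not per cell.
#'
#' The search is run with the biome's already-included environmental
#' constraints applied (their curves held fixed): the upper capacity
#' percentiles are only optimal because the scalars explain the suppressed
#' part of the data, so excluding them would bias the selection low.
#'
#' @param estimates Semi-monthly estimates from [estimate_fopt_alpha()]
#'   (with `ndvi`).
#' @param series Daily evaluation `site_daily_series` with `ndvi`.
#' @param fopt_grid,alpha_grid Percentile grids; default `seq(5, 100, 5)`.
#' @param n_bins NDVI bin count; default 20.
#' @param min_count Minimum bin occupancy; default 5.
#' @param constraints List of [constraint_spec()]s applied (fixed) while
#'   the NDVI-coupling percentiles vary; default none.
#' @return A list: `surface` (RMSE matrix, rows = fopt grid, cols = alpha
#'   grid), `fopt_pct`, `alpha_pct` (selected), `fopt_curve`, `alpha_curve`
#'   (refit at the selection), `max_binned_alpha`.
#' @export
percentile_sensitivity <- function(estimates, series,
                                   fopt_grid = seq(5, 100, 5),
                                   alpha_grid = seq(5, 100, 5),
                                   n_bins = 20, min_count = 5,
                                   constraints = list()) {
  if (!"ndvi" %in% names(series)) stop("series lacks an ndvi column")
  ok_f <- is.finite(estimates$ndvi) & is.finite(estimates$fopt)
  ok_a <- is.finite(estimates$ndvi) & is.finite(estimates$alpha)
  obs <- series$gpp_obs
  par <- series$par
  ndvi <- series$ndvi
  fopt_curves <- lapply(fopt_grid, function(p) {
    bp <- bin_percentile(estimates$ndvi[ok_f], estimates$fopt[ok_f],
                         level = p, n_bins = n_bins, min_count = min_count)
    fit_logistic(bp)
  })
  alpha_curves <- lapply(alpha_grid, function(p) {
    bp <- bin_percentile(estimates$ndvi[ok_a], estimates$alpha[ok_a],
                         level = p, n_bins = n_bins, min_count = min_count)
    fit_logistic(bp)
  })
  fopt_daily <- lapply(fopt_curves, function(f)
    if (f$converged) logistic_response(f$curve, ndvi) else NULL)
  alpha_daily <- lapply(alpha_curves, function(f)
    if (f$converged) pmin(logistic_response(f$curve, ndvi), 0.25) else NULL)
  surface <- matrix(NA_real_, length(fopt_grid), length(alpha_grid),
                    dimnames = list(fopt_grid, alpha_grid))
  okd <- is.finite(obs) & is.finite(par) & is.finite(ndvi)
  cv <- if (length(constraints)) {
    constraint_values(list(constraints = constraints), series)
  } else NULL
  for (i in seq_along(fopt_grid)) {
    fo <- fopt_daily[[i]]
    if (is.null(fo)) next
    for (j in seq_along(alpha_grid)) {
      al <- alpha_daily[[j]]
      if (is.null(al)) next
      gpp <- fo * (1 - exp(-al * par / fo))
      if (!is.null(cv)) gpp <- constrain_gpp(gpp, cv$scalars, cv$boundaries)
      surface[i, j] <- sqrt(mean((gpp[okd] - obs[okd])^2))
    }
  }
  if (all(is.na(surface))) stop("no percentile pair produced a valid fit")
  # arg-min with ties toward the lowest percentiles: scan in index order
  best <- which(surface == min(surface, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(surface = surface,
       fopt_pct = fopt_grid[best[1]], alpha_pct = alpha_grid[best[2]],
       fopt_curve = fopt_curves[[best[1]]]$curve,
       alpha_curve = alpha_curves[[best[2]]]$curve,
       max_binned_alpha = suppressWarnings(
         max(bin_percentile(estimates$ndvi[ok_a], estimates$alpha[ok_a],
                            level = alpha_grid[best[2]], n_bins = n_bins,
                            min_count = min_count)$value, na.rm = TRUE)))
}

#' Full calibration workflow for one biome
#'
#' Runs the complete chain on a list of quality-controlled site records:
#' semi-monthly F_opt/alpha extraction, initial NDVI couplings (95th/50th
#' percentiles), regression-tree variable importance of the GPP scalar,
#' constraint inclusion in importance order (with optional scalar
#' percentile search), the F_opt/alpha percentile sensitivity search with
#' the retained constraints applied, a constraint rebuild against the
#' selected curves, and finally the bootstrap parameterization.
#'
#' @param sites List of `site_daily_series` with daily `ndvi` attached.
#' @param quality_threshold Quality-flag threshold; default 0.5.
#' @param fopt_level,low_light_par,alpha_cap Semi-monthly extraction
#'   settings (see [estimate_fopt_alpha()]).
#' @param n_bins,min_count NDVI binning controls.
#' @param fopt_grid,alpha_grid Percentile grids for the sensitivity search.
#' @param scalar_grid Percentile level(s) for constraint scalars.
#' @param ranking Driver ranking; NULL (default) ranks by
#'   [variable_importance()].
#' @param include_co2 Offer the CO2 constraint as a candidate? Default
#'   FALSE (it degrades performance and is excluded).
#' @param apply_alpha_limit Cap predicted alpha at the maximum binned
#'   alpha (used for sparsely sampled deciduous forests)? Default FALSE.
#' @param n_iter,seed Bootstrap controls; `n_iter = 0` skips the bootstrap
#'   and returns the template fit as the model.
#' @param eps GPP-scalar epsilon.
#' @return A list: `model` (bootstrap-mean `biome_model`), `template`
#'   (pre-bootstrap model), `sensitivity`, `importance`, `bootstrap`,
#'   `estimates`.
#' @export
calibrate_biome <- function(sites, quality_threshold = 0.5, fopt_level = 95,
                            low_light_par = 25, alpha_cap = 0.25,
                            n_bins = 20, min_count = 5,
                            fopt_grid = seq(5, 100, 5),
                            alpha_grid = seq(5, 100, 5), scalar_grid = 50,
                            ranking = NULL, include_co2 = FALSE,
                            apply_alpha_limit = FALSE, n_iter = 200,
                            seed = 1, eps = 0.1) {
  if (is.data.frame(sites)) sites <- list(sites)
  sites <- lapply(sites, quality_filter, threshold = quality_threshold)
  pooled <- do.call(rbind, sites)
  est <- estimate_fopt_alpha(pooled, fopt_level, low_light_par, alpha_cap)
  cf0 <- fit_ndvi_curves(est, 95, 50, n_bins, min_count)
  if (!cf0$fopt$converged || !cf0$alpha$converged)
    stop("initial NDVI coupling fit failed: ", cf0$fopt$flag, " / ",
         cf0$alpha$flag)
  m0 <- biome_model(pooled$biome[1], cf0$fopt$curve, cf0$alpha$curve)
  vars <- c("t_air", "swc", "vpd", if (include_co2) "co2")
  importance <- NULL
  if (is.null(ranking)) {
    scal <- gpp_scalar(pooled, m0, eps = eps)
    importance <- tryCatch(
      variable_importance(scal, pooled[vars], seed = seed),
      error = function(e) NULL, warning = function(w) NULL)
    ranking <- if (!is.null(importance)) names(importance) else vars
  }
  m0 <- build_constraints(pooled, m0, ranking = ranking,
                          scalar_grid = scalar_grid, min_count = min_count,
                          eps = eps)
  sens <- percentile_sensitivity(est, pooled, fopt_grid, alpha_grid,
                                 n_bins = n_bins, min_count = min_count,
                                 constraints = m0$constraints)
  template <- biome_model(
    pooled$biome[1], sens$fopt_curve, sens$alpha_curve,
    alpha_limit = if (apply_alpha_limit) sens$max_binned_alpha,
    selected_percentiles = list(fopt = sens$fopt_pct, alpha = sens$alpha_pct,
                                scalars = list()))
  template <- build_constraints(pooled, template, ranking = ranking,
                                scalar_grid = scalar_grid,
                                min_count = min_count, eps = eps)
  template$selected_percentiles$fopt <- sens$fopt_pct
  template$selected_percentiles$alpha <- sens$alpha_pct
  if (n_iter > 0) {
    boot <- bootstrap_calibrate(sites, template, n_iter = n_iter,
                                seed = seed, n_bins = n_bins,
                                min_count = min_count)
    model <- boot$model
  } else {
    boot <- NULL
    model <- template
  }
  list(model = model, template = template, sensitivity = sens,
       importance = importance, bootstrap = boot, estimates = est)
}

split_site_years <- function(series) {
  yr <- as.POSIXlt(series$date)$year + 1900L
  lapply(split(seq_len(nrow(series)), interaction(series$site_id, yr,
                                                  drop = TRUE)),
         function(i) series[i, ])
}

refit_model_like <- function(template, train, fopt_pct, alpha_pct,
                             n_bins = 20, min_count = 5,
                             apply_alpha_limit = !is.null(template$alpha_limit),
                             eps = 0.1) {
  est <- estimate_fopt_alpha(train)
  cf <- fit_ndvi_curves(est, fopt_pct, alpha_pct, n_bins, min_count)
  if (!cf$fopt$converged || !cf$alpha$converged) return(NULL)
  m <- biome_model(template$biome, cf$fopt$curve, cf$alpha$curve,
                   alpha_limit = if (apply_alpha_limit) cf$max_binned_alpha,
                   selected_percentiles = template$selected_percentiles)
  scal <- gpp_scalar(train, m, eps = eps)
  for (cs in template$constraints) {
    resp <- if (cs$mode == "scalar") scal else train$gpp_obs
    lev <- if (cs$mode == "scalar") {
      lv <- template$selected_percentiles$scalars[[cs$variable]]
      if (is.null(lv)) 50 else lv
    } else 98
    curve <- fit_constraint_curve(train[[cs$variable]], resp, cs$variable,
                                  lev, min_count)
    if (is.null(curve)) next # keep the template's curve for this iteration
    if (cs$mode == "scalar") curve <- normalize_scalar_curve(curve)
    m <- with_constraint(m, constraint_spec(cs$variable, cs$mode, curve))
  }
  m
}

model_param_vector <- function(model) {
  out <- c(fopt_a_max = model$fopt_curve$a_max, fopt_k = model$fopt_curve$k,
           fopt_x_mid = model$fopt_curve$x_mid,
           alpha_a_max = model$alpha_curve$a_max,
           alpha_k = model$alpha_curve$k,
           alpha_x_mid = model$alpha_curve$x_mid)
  if (!is.null(model$alpha_limit)) out <- c(out, alpha_limit = model$alpha_limit)
  for (cs in model$constraints) {
    pfx <- paste0(cs$variable, "_", if (cs$mode == "scalar") "s" else "b", "_")
    cv <- cs$curve
    out <- c(out, stats::setNames(unlist(cv), paste0(pfx, names(cv))))
  }
  out
}

#' Bootstrap parameterization and cross-evaluation of a biome model
#'
#' Resamples calibration sites with replacement (or site-years when only
#' one site exists), refits every curve of the model template on the
#' included data and evaluates on the omitted sites (RMSE, OLS slope,
#' intercept, R2, bias, mean GPP). Iterations whose resample omits nothing
#' are redrawn. Final parameters are the means across iterations and the
#' parameter uncertainties their standard deviations; the run is fully
#' reproducible from the seed.
#'
#' @param sites List of `site_daily_series` (one per site, with `ndvi`), or
#'   a single series (then site-years are resampled).
#' @param template A `biome_model` defining the constraint set, selected
#'   percentiles and whether an alpha limit applies.
#' @param n_iter Number of bootstrap iterations; default 200.
#' @param seed RNG seed; default 1.
#' @param n_bins,min_count NDVI binning controls.
#' @return A list of class `bootstrap_calibration`: `model` (the template
#'   with mean parameters and `uncertainty` filled), `report` (per-iteration
#'   statistics on withheld data), `summary` (mean and SD of the report
#'   columns), `params` (per-iteration parameter draws).
#' @export
bootstrap_calibrate <- function(sites, template, n_iter = 200, seed = 1,
                                n_bins = 20, min_count = 5) {
  if (is.data.frame(sites)) sites <- list(sites)
  units <- if (length(sites) >= 2) sites else split_site_years(sites[[1]])
  if (length(units) < 2) stop("need >= 2 sites or site-years")
  n <- length(units)
  pf <- template$selected_percentiles$fopt
  pa <- template$selected_percentiles$alpha
  set.seed(seed)
  params <- list(); report <- list()
  it <- 0
  attempts <- 0
  while (it < n_iter) {
    attempts <- attempts + 1
    if (attempts > 20 * n_iter + 50)
      stop("bootstrap could not complete: curve refits keep failing ",
           "(data too sparse for the configured binning?)")
    idx <- sample.int(n, n, replace = TRUE)
    omit <- setdiff(seq_len(n), unique(idx))
    if (!length(omit)) next # nothing withheld: resample
    train <- do.call(rbind, units[idx])
    m <- refit_model_like(template, train, pf, pa, n_bins, min_count)
    if (is.null(m)) next
    it <- it + 1
    test <- do.call(rbind, units[omit])
    mod <- model_gpp(m, test)
    ok <- is.finite(mod) & is.finite(test$gpp_obs)
    st <- ols_stats(mod[ok], test$gpp_obs[ok])
    params[[it]] <- model_param_vector(m)
    report[[it]] <- data.frame(iteration = it, mean_gpp = mean(mod[ok]),
                               bias = st$bias, rmse = st$rmse,
                               slope = st$slope, intercept = st$intercept,
                               r_squared = st$r_squared, n = st$n,
                               omitted = paste(sort(omit), collapse = ";"))
  }
  nms <- unique(unlist(lapply(params, names)))
  pm <- t(vapply(params, function(p) p[nms], numeric(length(nms))))
  colnames(pm) <- nms
  means <- colMeans(pm, na.rm = TRUE)
  sds <- apply(pm, 2, stats::sd, na.rm = TRUE)
  final <- template
  final$fopt_curve <- logistic_curve(means[["fopt_a_max"]], means[["fopt_k"]],
                                     means[["fopt_x_mid"]])
  final$alpha_curve <- logistic_curve(means[["alpha_a_max"]],
                                      means[["alpha_k"]],
                                      means[["alpha_x_mid"]])
  if ("alpha_limit" %in% nms) final$alpha_limit <- means[["alpha_limit"]]
  final$constraints <- lapply(template$constraints, function(cs) {
    pfx <- paste0(cs$variable, "_", if (cs$mode == "scalar") "s" else "b", "_")
    if (inherits(cs$curve, "logistic_curve")) {
      cs$curve <- logistic_curve(means[[paste0(pfx, "a_max")]],
                                 means[[paste0(pfx, "k")]],
                                 means[[paste0(pfx, "x_mid")]])
      if (cs$mode == "scalar") cs$curve <- normalize_scalar_curve(cs$curve)
    } else {
      cs$curve <- gaussian_curve(means[[paste0(pfx, "a_max")]],
                                 means[[paste0(pfx, "b_mid")]],
                                 means[[paste0(pfx, "b_sigma")]])
      if (cs$mode == "scalar") cs$curve <- normalize_scalar_curve(cs$curve)
    }
    cs
  })
  final$uncertainty <- sds
  rep_df <- do.call(rbind, report)
  stat_cols <- setdiff(names(rep_df), c("iteration", "n", "omitted"))
  summ <- data.frame(
    statistic = stat_cols,
    mean = vapply(stat_cols, function(c) mean(rep_df[[c]]), 0),
    sd = vapply(stat_cols, function(c) stats::sd(rep_df[[c]]), 0))
  rownames(summ) <- NULL
  structure(list(model = final, report = rep_df, summary = summ, params = pm),
            class = "bootstrap_calibration")
}
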
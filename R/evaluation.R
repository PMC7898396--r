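#' Ordinary least squares agreement statistics
#'
#' Regresses model on reference (reference on the x-axis) and reports the
#' slope, intercept and R2 of the fit together with the RMSE and bias
#' (mean model minus reference) of the raw pairs, not of the fit.
#'
#' @param model_values Modelled values.
#' @param reference_values Reference values (paired, >= 3 points).
#' @return A list of class `evaluation_stats`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `bias`, `n`. A zero-variance reference leaves the
#'   regression fields NA with a `flag`.
#' @export
ols_stats <- function(model_values, reference_values) {
  ok <- is.finite(model_values) & is.finite(reference_values)
  m <- model_values[ok]; r <- reference_values[ok]
  n <- length(m)
  if (n < 3) stop("need >= 3 paired points")
  rmse <- sqrt(mean((m - r)^2))
  bias <- mean(m - r)
  if (stats::sd(r) < 1e-12 * max(abs(r), 1)) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, rmse = rmse, bias = bias,
                          n = n, flag = "zero-variance reference"),
                     class = "evaluation_stats"))
  }
  fit <- stats::lm(m ~ r)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(m) < 1e-12 * max(abs(m), 1)) 0
        else stats::cor(m, r)^2
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, rmse = rmse, bias = bias, n = n,
                 flag = "ok"),
            class = "evaluation_stats")
}

#' Spatial / inter-annual / intra-annual evaluation decomposition
#'
#' Splits paired per-site daily time series of model and reference into the
#' three classic evaluation axes: spatial (per-site all-time means, one
#' pair per site), inter-annual (per-year across-site means, one pair per
#' year) and intra-annual (per-day-of-year across-site means, at most 366
#' pairs). Each paired set is summarized with [ols_stats()].
#'
#' @param df A data.frame with columns `site_id`, `date` (Date), `model`,
#'   `reference`.
#' @return A list with elements `spatial`, `interannual`, `intraannual`;
#'   each holds `pairs` (the aggregated data.frame) and `stats`.
#' @export
decompose_evaluation <- function(df) {
  stopifnot(all(c("site_id", "date", "model", "reference") %in% names(df)),
            inherits(df$date, "Date"))
  ok <- is.finite(df$model) & is.finite(df$reference)
  df <- df[ok, ]
  if (length(unique(df$site_id)) < 2) stop("need >= 2 sites")
  lt <- as.POSIXlt(df$date)
  year <- lt$year + 1900L
  if (length(unique(year)) < 2) stop("need >= 2 years")
  doy <- lt$yday + 1L
  agg <- function(key) {
    m <- tapply(df$model, key, mean)
    r <- tapply(df$reference, key, mean)
    data.frame(key = names(m), model = as.numeric(m),
               reference = as.numeric(r))
  }
  # a fit is only reported for > 2 pairs; RMSE and bias are always defined
  pair_stats <- function(p) {
    if (nrow(p) >= 3) return(ols_stats(p$model, p$reference))
    structure(list(slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_,
                   rmse = sqrt(mean((p$model - p$reference)^2)),
                   bias = mean(p$model - p$reference), n = nrow(p),
                   flag = "fewer than 3 pairs"),
              class = "evaluation_stats")
  }
  out <- lapply(list(spatial = agg(df$site_id), interannual = agg(year),
                     intraannual = agg(doy)),
                function(p) list(pairs = p, stats = pair_stats(p)))
  out
}

#' Compare annual GPP with annual NPP against the 2:1 expectation
#'
#' NPP is roughly half of GPP, so paired annual sums should scatter around
#' the two-to-one line. Reports OLS statistics of GPP against NPP, the mean
#' GPP/NPP ratio and the fraction of pairs whose ratio falls within
#' `band` of 2.
#'
#' @param annual_gpp,annual_npp Paired annual sums (g C m-2 yr-1).
#' @param band Half-width of the acceptance band around 2; default 0.5.
#' @return A list: `stats` ([ols_stats()] of GPP on NPP, or NULL when fewer
#'   than 3 pairs overlap), `mean_ratio`, `frac_within_band`, `n`.
#' @export
npp_ratio_check <- function(annual_gpp, annual_npp, band = 0.5) {
  ok <- is.finite(annual_gpp) & is.finite(annual_npp) & annual_npp > 0
  g <- annual_gpp[ok]; p <- annual_npp[ok]
  if (length(g) == 0) {
    return(list(stats = NULL, mean_ratio = NA_real_,
                frac_within_band = NA_real_, n = 0L))
  }
  ratio <- g / p
  list(stats = if (length(g) >= 3) ols_stats(g, p) else NULL,
       mean_ratio = mean(ratio),
       frac_within_band = mean(abs(ratio - 2) <= band),
       n = length(g))
}
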
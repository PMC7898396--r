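#' Ground-truth configuration for the synthetic-data generator
#'
#' Defines a complete, known forward model and driver climatology from
#' which site records and gridded scenes are generated. The defaults
#' emulate a seasonally green, mostly sunny ecosystem and were chosen so
#' that the calibration conventions are unbiased against the truth:
#'
#' * quantum efficiency is tied to capacity through a fixed saturation
#'   ratio `sat_ratio` = F_opt/alpha (W m-2), so clear-sky PAR drives the
#'   light response to ~90% of saturation in every season and the
#'   semi-monthly 95th-percentile capacity estimate reaches the true curve;
#' * the truth's environmental constraints (none by default; see
#'   [synthetic_truth_tair_stress()] for a preset with a strong
#'   air-temperature scalar) are applied to GPP exactly as the calibrated
#'   model applies them; an optional random semi-monthly capacity stress
#'   (uniform on `stress_range`, capped at 1) can add unexplainable
#'   variation and is disabled by default;
#' * deep-overcast (low-light) days follow the seasonal greenness, i.e.
#'   they fall in the warm wet season where the temperature scalar is
#'   near one, so the low-light GPP/PAR ratios estimate alpha without
#'   constraint-induced bias;
#' * heavily overcast days (transmittance below `diffuse_threshold`)
#'   carry a diffuse-light enhancement of quantum efficiency,
#'   `1 + diffuse_enhancement * (diffuse_threshold - tau) /
#'   diffuse_threshold`, sized so that the median low-light GPP/PAR secant
#'   is an unbiased estimator of true alpha (diffuse sky raises canopy
#'   light-use efficiency, and the effect is concentrated where the
#'   diffuse fraction approaches one).
#'
#' Flux noise is multiplicative mean-one lognormal (keeps GPP
#' nonnegative); daily meteorology carries AR(1) persistence 0.7.
#'
#' @param biome Biome name (one of [biome_names()]).
#' @param fopt_max,fopt_k,fopt_mid True capacity-NDVI logistic parameters.
#' @param sat_ratio F_opt/alpha, W m-2; sets the PAR saturation scale.
#' @param ndvi_base,ndvi_amp,greenup_sm,senescence_sm,ndvi_rate Seasonal
#'   NDVI double-logistic shape (semi-month index 1..24).
#' @param ndvi_noise_sd,ndvi_dropout Composite noise SD and missing
#'   probability for the observed NDVI series.
#' @param sw_mean,sw_amp,sw_peak_doy Clear-sky shortwave climatology,
#'   W m-2.
#' @param p_clear,clear_tau,cloudy_tau Semi-monthly cloud regime: fraction
#'   of clear periods and transmittance ranges.
#' @param tau_jitter Daily lognormal jitter SD on transmittance.
#' @param p_deep,deep_tau Mean probability and transmittance range of deep
#'   overcast days (the low-light days supporting alpha estimation); the
#'   daily probability follows the seasonal greenness shape (monsoon-like
#'   clouding in the growing season).
#' @param diffuse_enhancement,diffuse_threshold Overcast
#'   quantum-efficiency enhancement coefficient and the transmittance
#'   below which it applies (see Details).
#' @param stress_range Range of the optional random semi-monthly capacity
#'   stress factor before capping at 1; `c(1, 1)` (default) disables it.
#' @param t_mean,t_amp,t_sd T_air climatology, degC; `met_ar1` applies.
#' @param swc_mean,swc_amp,swc_sd SWC climatology, %Vol.
#' @param vpd_mean,vpd_amp,vpd_sd VPD climatology, hPa.
#' @param co2_start,co2_trend,co2_sd CO2 level, ppm (+trend per year).
#' @param met_ar1 AR(1) coefficient of daily meteorology noise.
#' @param flux_noise_sd Lognormal sigma of multiplicative GPP noise.
#' @param alpha_day_sd Lognormal sigma (median-one) of day-to-day
#'   physiological variability in quantum efficiency; widens the scatter
#'   of low-light alpha estimates the way real canopies do.
#' @param qc_dropout Probability of a low quality flag on a day.
#' @param constraints List of true [constraint_spec()]s applied to GPP
#'   (e.g. an air-temperature scalar).
#' @return An object of class `synthetic_truth` (also carries the derived
#'   `fopt_curve` and `alpha_curve`).
#' @export
synthetic_truth <- function(biome = "savannah_shrublands",
                            fopt_max = 8, fopt_k = 10, fopt_mid = 0.55,
                            sat_ratio = 80,
                            ndvi_base = 0.30, ndvi_amp = 0.45,
                            greenup_sm = 8, senescence_sm = 18,
                            ndvi_rate = 0.9,
                            ndvi_noise_sd = 0.012, ndvi_dropout = 0.08,
                            sw_mean = 260, sw_amp = 15, sw_peak_doy = 200,
                            p_clear = 0.2, clear_tau = c(0.88, 0.98),
                            cloudy_tau = c(0.30, 0.75), tau_jitter = 0.08,
                            p_deep = 0.05, deep_tau = c(0.02, 0.12),
                            diffuse_enhancement = 0.12,
                            diffuse_threshold = 0.25,
                            stress_range = c(1, 1),
                            t_mean = 22, t_amp = 6, t_sd = 1.5,
                            swc_mean = 22, swc_amp = 5, swc_sd = 4,
                            vpd_mean = 10, vpd_amp = 5, vpd_sd = 3,
                            co2_start = 380, co2_trend = 2, co2_sd = 1.5,
                            met_ar1 = 0.7,
                            flux_noise_sd = 0.10, alpha_day_sd = 0.30,
                            qc_dropout = 0.10,
                            constraints = list()) {
  out <- as.list(environment())
  out$fopt_curve <- logistic_curve(fopt_max, fopt_k, fopt_mid)
  out$alpha_curve <- logistic_curve(fopt_max / sat_ratio, fopt_k, fopt_mid)
  class(out) <- "synthetic_truth"
  out
}

#' Truth preset with a known air-temperature suppression
#'
#' A cool-climate grassland truth whose GPP carries a strong logistic
#' air-temperature scalar while SWC and VPD are generated without any
#' effect on GPP: the constraint-inclusion logic should retain exactly the
#' T_air scalar.
#'
#' @param ... Overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @export
synthetic_truth_tair_stress <- function(...) {
  args <- list(biome = "grasslands", t_mean = 12, t_amp = 12, t_sd = 2,
               constraints = list(constraint_spec(
                 "t_air", "scalar", logistic_curve(1, 0.35, 12))))
  args[names(list(...))] <- list(...)
  do.call(synthetic_truth, args)
}

ar1_noise <- function(n, sd, phi) {
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

lognormal_mean_one <- function(n, sd) {
  if (sd <= 0) return(rep(1, n))
  stats::rlnorm(n, -sd^2 / 2, sd)
}

ndvi_shape <- function(sm, truth) {
  1 / (1 + exp(-truth$ndvi_rate * (sm - truth$greenup_sm))) -
    1 / (1 + exp(-truth$ndvi_rate * (sm - truth$senescence_sm)))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

gen_site_impl <- function(truth, site_id, n_years, start_year,
                          ndvi_base_shift = 0, t_shift = 0,
                          ndvi_amp_scale = rep(1, n_years)) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  nd <- length(dates)
  lt <- as.POSIXlt(dates)
  doy <- lt$yday + 1
  yr_idx <- lt$year + 1900 - start_year + 1
  sm <- semimonth_of(dates)
  sm_key <- paste(sm$year, sm$sm)
  sm_levels <- unique(sm_key)
  sm_idx <- match(sm_key, sm_levels)
  n_sm <- length(sm_levels)
  # true semi-monthly NDVI (per-year amplitude scaling drives trends)
  sm_tab <- unique(data.frame(year = sm$year, smno = sm$sm))
  amp_y <- truth$ndvi_amp * ndvi_amp_scale[sm_tab$year - start_year + 1]
  ndvi_true_sm <- pmin(truth$ndvi_base + ndvi_base_shift +
                         amp_y * ndvi_shape(sm_tab$smno, truth), 0.98)
  ndvi_daily <- ndvi_true_sm[sm_idx]
  # cloud transmittance: semi-monthly regime + daily jitter + deep overcast
  clear <- stats::runif(n_sm) < truth$p_clear
  tau_sm <- ifelse(clear,
                   stats::runif(n_sm, truth$clear_tau[1], truth$clear_tau[2]),
                   stats::runif(n_sm, truth$cloudy_tau[1],
                                truth$cloudy_tau[2]))
  tau <- pmin(tau_sm[sm_idx] *
                stats::rlnorm(nd, 0, truth$tau_jitter), 1)
  # deep overcast follows the greenness season (monsoon-like clouding)
  shape_d <- ndvi_shape(sm$sm, truth)
  w_deep <- shape_d / max(mean(shape_d), 1e-6)
  deep <- stats::runif(nd) < truth$p_deep * w_deep
  tau[deep] <- stats::runif(sum(deep), truth$deep_tau[1], truth$deep_tau[2])
  sw_clear <- truth$sw_mean +
    truth$sw_amp * cos(2 * pi * (doy - truth$sw_peak_doy) / 365.25)
  par <- shortwave_to_par(sw_clear * tau)
  # meteorology: seasonal cycle (in phase with radiation) + AR(1) noise
  seas <- cos(2 * pi * (doy - truth$sw_peak_doy) / 365.25)
  t_air <- truth$t_mean + t_shift + truth$t_amp * seas +
    ar1_noise(nd, truth$t_sd, truth$met_ar1)
  swc <- pmax(truth$swc_mean - truth$swc_amp * seas +
                ar1_noise(nd, truth$swc_sd, truth$met_ar1), 1)
  vpd <- pmax(truth$vpd_mean + truth$vpd_amp * seas +
                ar1_noise(nd, truth$vpd_sd, truth$met_ar1), 0)
  co2 <- truth$co2_start + truth$co2_trend * (yr_idx - 1) +
    stats::rnorm(nd, 0, truth$co2_sd)
  # optional random capacity stress: semi-monthly, uniform capped at one
  u_sm <- pmin(stats::runif(n_sm, truth$stress_range[1],
                            truth$stress_range[2]), 1)
  u <- u_sm[sm_idx]
  # forward model: stressed capacity, diffuse-enhanced quantum efficiency
  fopt_d <- logistic_response(truth$fopt_curve, ndvi_daily) * u
  diffuse <- pmax(truth$diffuse_threshold - tau, 0) / truth$diffuse_threshold
  alpha_d <- logistic_response(truth$alpha_curve, ndvi_daily) *
    (1 + truth$diffuse_enhancement * diffuse) *
    stats::rlnorm(nd, 0, truth$alpha_day_sd)
  gpp_true <- lrf_gpp(fopt_d, alpha_d, par)
  if (length(truth$constraints)) {
    drv <- data.frame(t_air = t_air, swc = swc, vpd = vpd, co2 = co2)
    cv <- constraint_values(list(constraints = truth$constraints), drv)
    gpp_true <- constrain_gpp(gpp_true, cv$scalars, cv$boundaries)
  }
  gpp_obs <- gpp_true * lognormal_mean_one(nd, truth$flux_noise_sd)
  quality_flag <- ifelse(stats::runif(nd) < truth$qc_dropout, 0.3, 1)
  series <- site_daily_series(data.frame(
    site_id = site_id, biome = truth$biome, date = dates, gpp_obs = gpp_obs,
    quality_flag = quality_flag, par = par, t_air = t_air, swc = swc,
    vpd = vpd, co2 = co2))
  series$ndvi <- ndvi_daily
  # observed NDVI composites: noise + missing composites
  ndvi_obs <- ndvi_true_sm + stats::rnorm(n_sm, 0, truth$ndvi_noise_sd)
  ndvi_obs[stats::runif(n_sm) < truth$ndvi_dropout] <- NA
  ndvi_obs <- pmin(pmax(ndvi_obs, -0.2), 1)
  ns <- ndvi_series(sm_tab$year, (sm_tab$smno + 1) %/% 2,
                    2 - sm_tab$smno %% 2, ndvi_obs)
  ns_true <- ndvi_series(sm_tab$year, (sm_tab$smno + 1) %/% 2,
                         2 - sm_tab$smno %% 2, ndvi_true_sm)
  list(series = series, gpp_true = gpp_true, ndvi_true = ns_true,
       ndvi_obs = ns, stress = u_sm, tau = tau)
}

#' Generate one synthetic site record
#'
#' Draws a daily driver and flux record of `n_years` from the truth's
#' generators: seasonal NDVI (with a noisy, gappy observed composite series
#' alongside the clean truth), cloud-modulated PAR, AR(1) meteorology,
#' true GPP from the full forward model and observed GPP with mean-one
#' lognormal noise and quality-flag dropout. Reproducible from the seed;
#' the global RNG state is untouched.
#'
#' @param truth A [synthetic_truth()].
#' @param site_id Site identifier string.
#' @param n_years Number of full calendar years (>= 1).
#' @param seed RNG seed.
#' @param start_year First calendar year; default 2001.
#' @param site_spread Draw small site-specific NDVI and temperature
#'   offsets? Default TRUE.
#' @return A list: `series` (a `site_daily_series` with true daily NDVI
#'   attached), `gpp_true` (noise-free daily GPP), `ndvi_true` and
#'   `ndvi_obs` (semi-monthly [ndvi_series()]), `stress`, `tau`.
#' @export
gen_site <- function(truth, site_id = "SYN-001", n_years = 3, seed = 1,
                     start_year = 2001, site_spread = TRUE) {
  stopifnot(n_years >= 1)
  with_seed(seed, {
    shift_n <- if (site_spread) stats::runif(1, -0.03, 0.03) else 0
    shift_t <- if (site_spread) stats::runif(1, -2, 2) else 0
    gen_site_impl(truth, site_id, n_years, start_year,
                  ndvi_base_shift = shift_n, t_shift = shift_t)
  })
}

#' Generate a calibration ensemble of synthetic sites
#'
#' @param truth A [synthetic_truth()].
#' @param n_sites Number of sites; default 12.
#' @param n_years Years per site; default 3.
#' @param seed Base seed; site i uses `seed * 1000 + i`.
#' @return A list of [gen_site()] results, one per site.
#' @export
gen_sites <- function(truth, n_sites = 12, n_years = 3, seed = 1) {
  lapply(seq_len(n_sites), function(i)
    gen_site(truth, sprintf("SYN-%03d", i), n_years,
             seed = seed * 1000 + i))
}

#' Generate a gridded synthetic scene with known budgets
#'
#' Builds co-registered NDVI, PAR, T_air, SWC and VPD driver fields plus a
#' biome map over a small lat/lon window, with every cell drawn from the
#' same truth (cell-specific seeds). A multiplicative per-year ramp on the
#' NDVI amplitude imposes a known-sign budget trend, and a lognormal
#' perturbation of amplitude `iav_sd` adds inter-annual variability. True
#' (noise-free) daily GPP fields and their annual budgets are returned for
#' recovery tests.
#'
#' @param truth A [synthetic_truth()].
#' @param lat,lon Cell-centre coordinates of the scene.
#' @param n_years Number of years.
#' @param budget_trend Fractional NDVI-amplitude ramp per year (e.g. 0.01).
#' @param iav_sd Lognormal SD of the per-year amplitude perturbation.
#' @param seed RNG seed.
#' @param start_year First year; default 2001.
#' @param frac_nonveg Fraction of cells set non-vegetated; default 0.1.
#' @return A list: `ndvi`, `par`, `t_air`, `swc`, `vpd`, `gpp_true`
#'   (daily `gridded_field`s), `biome_map`, `true_budget` (a
#'   `budget_series` from the true GPP), `amp_scale`.
#' @export
gen_grid <- function(truth, lat = seq(10, 19, by = 1),
                     lon = seq(20, 29, by = 1), n_years = 3,
                     budget_trend = 0, iav_sd = 0, seed = 1,
                     start_year = 2001, frac_nonveg = 0.1) {
  nlat <- length(lat); nlon <- length(lon)
  # build in the normalized (descending-latitude) orientation so the biome
  # map stays aligned with the gridded fields
  lat <- sort(as.numeric(lat), decreasing = TRUE)
  lon <- sort(as.numeric(lon))
  with_seed(seed, {
    amp_scale <- (1 + budget_trend * (seq_len(n_years) - 1)) *
      lognormal_mean_one(n_years, iav_sd)
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
                 by = "day")
    nt <- length(dates)
    ncell <- nlat * nlon
    nonveg <- stats::runif(ncell) < frac_nonveg
    biome_code <- match(truth$biome, biome_names())
    biome_map <- matrix(ifelse(nonveg, 0L, biome_code), nlat, nlon)
    mk <- function() array(NA_real_, c(nlat, nlon, nt))
    out <- list(ndvi = mk(), par = mk(), t_air = mk(), swc = mk(),
                vpd = mk(), gpp_true = mk())
    cell_seeds <- stats::runif(ncell)
    for (i in seq_len(ncell)) {
      r <- round(cell_seeds[i] * 1e8)
      cell <- with_seed(r, gen_site_impl(
        truth, sprintf("cell%04d", i), n_years, start_year,
        ndvi_base_shift = stats::runif(1, -0.03, 0.03),
        t_shift = stats::runif(1, -2, 2), ndvi_amp_scale = amp_scale))
      rc <- arrayInd(i, c(nlat, nlon))
      g <- if (nonveg[i]) rep(0, nt) else cell$gpp_true
      out$gpp_true[rc[1], rc[2], ] <- g
      out$ndvi[rc[1], rc[2], ] <- cell$series$ndvi
      out$par[rc[1], rc[2], ] <- cell$series$par
      out$t_air[rc[1], rc[2], ] <- cell$series$t_air
      out$swc[rc[1], rc[2], ] <- cell$series$swc
      out$vpd[rc[1], rc[2], ] <- cell$series$vpd
    }
    units <- c(ndvi = "1", par = "W m-2", t_air = "degC", swc = "%Vol",
               vpd = "hPa", gpp_true = "gC m-2 day-1")
    fields <- lapply(names(out), function(nm)
      gridded_field(out[[nm]], lat, lon, time = dates, units = units[[nm]]))
    names(fields) <- names(out)
    fields$biome_map <- biome_map
    fields$true_budget <- annual_budget(fields$gpp_true)
    fields$amp_scale <- amp_scale
    fields
  })
}
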
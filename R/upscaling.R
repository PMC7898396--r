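EARTH_RADIUS_M <- 6371000

#' Georeferenced raster stack
#'
#' A regular cell-centre-registered lat/lon grid with an optional time
#' axis. Values are stored as an array `[lat, lon]` or `[lat, lon, time]`.
#' Latitude must be strictly monotone; fields are normalized to descending
#' latitude (north up) on construction.
#'
#' @param values Matrix or 3-d array of cell values.
#' @param lat,lon Cell-centre coordinates, degrees; strictly monotone.
#' @param time Optional time axis (any vector; length = 3rd dim).
#' @param units Units string (required; no silent unit guessing).
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, time = NULL, units) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3, dim(values)[1] == length(lat),
            dim(values)[2] == length(lon))
  storage.mode(values) <- "double"
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (missing(units) || !nzchar(units)) stop("units attribute is required")
  dlat <- diff(lat)
  if (length(lat) > 1 && !(all(dlat > 0) || all(dlat < 0)))
    stop("latitude must be strictly monotone")
  if (length(lat) > 1 && all(dlat > 0)) { # normalize to descending latitude
    lat <- rev(lat)
    values <- values[rev(seq_along(lat)), , , drop = FALSE]
  }
  if (length(lon) > 1 && !all(diff(lon) > 0))
    stop("longitude must be strictly increasing")
  if (!is.null(time)) stopifnot(length(time) == dim(values)[3])
  structure(list(values = values, lat = lat, lon = lon, time = time,
                 units = units),
            class = "gridded_field")
}

#' Merge IGBP land cover classes into the eight modelled biomes
#'
#' Forest classes 1-5 are kept; closed/open shrublands and woody savannahs
#' (6-8) merge with savannahs (9); permanent wetlands (11) with grasslands
#' (10); cropland/natural mosaic (14) with croplands (12); urban, snow/ice
#' and barren (13, 15, 16) become non-vegetated (GPP not modelled,
#' contributes zero).
#'
#' @param igbp Matrix (or vector) of IGBP codes 1-16.
#' @return Integer map of the same shape: biome codes 1-8 (see
#'   [biome_names()]) with 0 for non-vegetated; attribute `biome_names`.
#' @export
merge_igbp <- function(igbp) {
  lut <- c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 6L, 6L, 7L, 7L, 8L, 0L, 8L, 0L, 0L)
  bad <- !is.na(igbp) & !(igbp %in% 1:16)
  if (any(bad))
    stop("unknown IGBP codes at cells: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  out <- igbp
  out[!is.na(igbp)] <- lut[igbp[!is.na(igbp)]]
  attr(out, "biome_names") <- biome_names()
  out
}

#' Names of the eight merged biomes
#'
#' @return Character vector indexed by biome code 1-8.
#' @export
biome_names <- function() {
  c("evergreen_needleleaf_forest", "evergreen_broadleaf_forest",
    "deciduous_needleleaf_forest", "deciduous_broadleaf_forest",
    "mixed_forest", "savannah_shrublands", "grasslands", "croplands")
}

#' Bilinear (or nearest-neighbour) regridding
#'
#' Continuous fields are interpolated bilinearly from the four surrounding
#' source cell centres; missing source cells propagate missing. Categorical
#' maps (`method = "nearest"`) use nearest-neighbour instead. Target points
#' outside the source cell-centre hull are missing.
#'
#' @param field A `gridded_field`.
#' @param lat_out,lon_out Target cell-centre coordinates.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A `gridded_field` on the target grid.
#' @export
regrid_bilinear <- function(field, lat_out, lon_out, method = "bilinear") {
  method <- match.arg(method, c("bilinear", "nearest"))
  if (max(lat_out) < min(field$lat) || min(lat_out) > max(field$lat) ||
      max(lon_out) < min(field$lon) || min(lon_out) > max(field$lon))
    stop("target grid does not overlap the source grid")
  nt <- dim(field$values)[3]
  # pracma::interp2 wants ascending axes; fields store descending latitude
  lat_src <- rev(field$lat)
  out <- array(NA_real_, c(length(lat_out), length(lon_out), nt))
  grid <- expand.grid(lat = lat_out, lon = lon_out) # lat varies fastest
  inside <- grid$lat >= min(lat_src) & grid$lat <= max(lat_src) &
    grid$lon >= min(field$lon) & grid$lon <= max(field$lon)
  for (t in seq_len(nt)) {
    z <- field$values[rev(seq_along(field$lat)), , t, drop = TRUE]
    if (is.null(dim(z))) z <- matrix(z, length(field$lat), length(field$lon))
    zi <- rep(NA_real_, nrow(grid))
    if (method == "bilinear") {
      zi[inside] <- pracma::interp2(x = field$lon, y = lat_src, Z = z,
                                    xp = grid$lon[inside],
                                    yp = grid$lat[inside], method = "linear")
    } else {
      ilat <- vapply(grid$lat[inside],
                     function(v) which.min(abs(lat_src - v)), 0L)
      ilon <- vapply(grid$lon[inside],
                     function(v) which.min(abs(field$lon - v)), 0L)
      zi[inside] <- z[cbind(ilat, ilon)]
    }
    out[, , t] <- matrix(zi, length(lat_out), length(lon_out))
  }
  gridded_field(out, lat_out, lon_out, field$time, field$units)
}

#' Spherical cell areas of a regular lat/lon grid
#'
#' Cell area = R^2 * dlambda * (sin(phi2) - sin(phi1)) on a spherical Earth
#' of radius 6371 km, with cell-centre registration.
#'
#' @param lat,lon Cell-centre coordinates, degrees (regular spacing).
#' @return Matrix `[lat, lon]` of areas in m^2.
#' @export
cell_areas <- function(lat, lon) {
  dlat <- if (length(lat) > 1) abs(stats::median(diff(lat))) else 180
  dlon <- if (length(lon) > 1) abs(stats::median(diff(lon))) else 360
  phi1 <- pmax(lat - dlat / 2, -90) * pi / 180
  phi2 <- pmin(lat + dlat / 2, 90) * pi / 180
  band <- EARTH_RADIUS_M^2 * (dlon * pi / 180) * abs(sin(phi2) - sin(phi1))
  matrix(band, length(lat), length(lon))
}

#' Run the calibrated models over a gridded scene
#'
#' For every vegetated cell and day: F_opt and alpha from the biome's NDVI
#' couplings (with the alpha cap where applicable), GPP from the light
#' response, then the biome's scalars and upper boundaries. Non-vegetated
#' cells contribute zero; missing drivers propagate missing. Fails before
#' computing if a biome on the map has no calibrated model.
#'
#' @param models Named list of `biome_model`s, names matching
#'   [biome_names()] codes present on the map (as character codes or
#'   names).
#' @param biome_map Integer matrix of biome codes (0 = non-vegetated),
#'   dimensioned like the grids.
#' @param ndvi,par,t_air,swc,vpd Co-registered `gridded_field`s with a
#'   shared daily time axis.
#' @return A `gridded_field` of daily GPP, g C m-2 day-1.
#' @export
run_grid <- function(models, biome_map, ndvi, par, t_air, swc, vpd) {
  flds <- list(ndvi = ndvi, par = par, t_air = t_air, swc = swc, vpd = vpd)
  dims <- dim(ndvi$values)
  for (f in flds) {
    if (!identical(dim(f$values), dims) || !identical(f$lat, ndvi$lat) ||
        !identical(f$lon, ndvi$lon))
      stop("driver grids are not co-registered")
  }
  stopifnot(identical(dim(biome_map), dims[1:2]))
  codes <- sort(unique(biome_map[biome_map > 0]))
  key <- function(b) {
    nm <- biome_names()[b]
    if (nm %in% names(models)) nm else as.character(b)
  }
  missing_models <- codes[!vapply(codes, function(b)
    key(b) %in% names(models), TRUE)]
  if (length(missing_models))
    stop("no calibrated model for biome(s): ",
         paste(biome_names()[missing_models], collapse = ", "))
  nt <- dims[3]
  ncell <- dims[1] * dims[2]
  out <- array(NA_real_, dims)
  flat <- lapply(flds, function(f) matrix(f$values, ncell, nt))
  gpp <- matrix(NA_real_, ncell, nt)
  gpp[biome_map == 0, ] <- 0
  for (b in codes) {
    cells <- which(biome_map == b)
    m <- models[[key(b)]]
    df <- data.frame(ndvi = as.vector(flat$ndvi[cells, ]),
                     par = as.vector(flat$par[cells, ]),
                     t_air = as.vector(flat$t_air[cells, ]),
                     swc = as.vector(flat$swc[cells, ]),
                     vpd = as.vector(flat$vpd[cells, ]))
    ok <- is.finite(df$ndvi) & is.finite(df$par)
    g <- rep(NA_real_, nrow(df))
    if (any(ok)) {
      pa <- predict_fopt_alpha(m, df$ndvi[ok])
      gv <- lrf_gpp(pa$fopt, pa$alpha, df$par[ok])
      if (length(m$constraints)) {
        cv <- constraint_values(m, df[ok, ])
        gv <- constrain_gpp(gv, cv$scalars, cv$boundaries)
      }
      g[ok] <- gv
    }
    gpp[cells, ] <- g
  }
  gridded_field(array(gpp, dims), ndvi$lat, ndvi$lon, ndvi$time,
                units = "gC m-2 day-1")
}

#' Annual area-integrated GPP budgets
#'
#' Budget = sum over cells and days of GPP x cell area, converted from
#' g C to Pg C (1e15). Missing cells are treated as zero contribution;
#' partial years are an error unless `allow_partial`.
#'
#' @param gpp A daily `gridded_field` (g C m-2 day-1) whose `time` is a
#'   `Date` vector.
#' @param allow_partial Allow years with fewer than 365 days; default
#'   FALSE.
#' @return A data.frame of class `budget_series` with `year` and `gpp_pgc`.
#' @export
annual_budget <- function(gpp, allow_partial = FALSE) {
  if (is.null(gpp$time) || !inherits(gpp$time, "Date"))
    stop("gpp field needs a Date time axis")
  area <- cell_areas(gpp$lat, gpp$lon)
  year <- as.POSIXlt(gpp$time)$year + 1900L
  counts <- table(year)
  if (!allow_partial && any(counts < 365))
    stop("partial year(s): ", paste(names(counts)[counts < 365],
                                    collapse = ", "))
  ncell <- length(area)
  flat <- matrix(gpp$values, ncell, length(gpp$time))
  daily <- colSums(flat * as.vector(area), na.rm = TRUE) # g C per day
  ann <- tapply(daily, year, sum) * 1e-15
  out <- data.frame(year = as.integer(names(ann)), gpp_pgc = as.numeric(ann))
  class(out) <- c("budget_series", "data.frame")
  out
}

#' Linear trend of an annual series
#'
#' Ordinary least squares of value on year; the slope standard error is the
#' usual OLS standard error.
#'
#' @param values Annual values (>= 3).
#' @param years Corresponding years; defaults to an index.
#' @return A list: `slope`, `intercept`, `se` (slope standard error).
#' @export
trend <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  if (sum(ok) < 3) stop("need >= 3 time points")
  fit <- stats::lm(values[ok] ~ years[ok])
  co <- summary(fit)$coefficients
  list(slope = co[2, 1], intercept = co[1, 1],
       se = if (nrow(co) > 1) co[2, 2] else NA_real_)
}

#' Detrended inter-annual variability
#'
#' Sample standard deviation (n - 1) of the residuals from the linear
#' trend; invariant to adding a constant or a linear ramp.
#'
#' @inheritParams trend
#' @return The residual standard deviation.
#' @export
detrended_iav <- function(values, years = seq_along(values)) {
  ok <- is.finite(values) & is.finite(years)
  if (sum(ok) < 3) stop("need >= 3 time points")
  fit <- stats::lm(values[ok] ~ years[ok])
  stats::sd(stats::residuals(fit))
}

#' Per-pixel linear trend of an annual stack
#'
#' @param field A `gridded_field` with an annual time axis.
#' @return A list of `gridded_field`s: `slope` (units yr-1) and `se`.
#' @export
trend_field <- function(field) {
  nt <- dim(field$values)[3]
  if (nt < 3) stop("need >= 3 time points")
  yrs <- seq_len(nt)
  flat <- matrix(field$values, ncol = nt)
  xc <- yrs - mean(yrs)
  sxx <- sum(xc^2)
  slope <- as.vector(flat %*% xc) / sxx
  fitted <- outer(rowMeans(flat), rep(1, nt)) + outer(slope, xc)
  rss <- rowSums((flat - fitted)^2)
  se <- sqrt(rss / (nt - 2) / sxx)
  dm <- dim(field$values)[1:2]
  list(slope = gridded_field(array(slope, c(dm, 1)), field$lat, field$lon,
                             units = paste(field$units, "yr-1")),
       se = gridded_field(array(se, c(dm, 1)), field$lat, field$lon,
                          units = paste(field$units, "yr-1")))
}

#' Area-weighted latitudinal profile
#'
#' Mean of a static field per latitude row, weighted by cell area, with
#' missing cells excluded; an all-missing row stays missing.
#'
#' @param field A `gridded_field` with a single time slice.
#' @return A data.frame with `lat` and `mean`.
#' @export
latitudinal_profile <- function(field) {
  stopifnot(dim(field$values)[3] == 1)
  area <- cell_areas(field$lat, field$lon)
  z <- field$values[, , 1, drop = TRUE]
  if (is.null(dim(z))) z <- matrix(z, length(field$lat), length(field$lon))
  prof <- vapply(seq_along(field$lat), function(i) {
    ok <- is.finite(z[i, ])
    if (!any(ok)) return(NA_real_)
    sum(z[i, ok] * area[i, ok]) / sum(area[i, ok])
  }, 0)
  data.frame(lat = field$lat, mean = prof)
}
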
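SITE_CSV_COLUMNS <- c(TIMESTAMP = "integer", GPP_DT_VUT_MEAN = "numeric",
                      GPP_QC = "numeric", SW_IN = "numeric", TA = "numeric",
                      SWC = "numeric", VPD = "numeric", CO2 = "numeric")

#' Read a daily site record from CSV
#'
#' Expects a FLUXNET-style layout with columns `TIMESTAMP` (YYYYMMDD
#' integer), `GPP_DT_VUT_MEAN` (g C m-2 day-1), `GPP_QC` (quality flag
#' 0..1), `SW_IN` (downwelling shortwave, W m-2), `TA` (degC), `SWC`
#' (%Vol), `VPD` (hPa), `CO2` (ppm) and optionally `SITE_ID`, `BIOME` and
#' `NDVI` (daily). Units are validated with plausibility ranges;
#' unparseable or out-of-range rows are dropped with a warning naming the
#' offending line numbers. PAR is derived from `SW_IN`.
#'
#' @param path CSV file path.
#' @param site_id,biome Defaults when the file lacks the columns.
#' @return A `site_daily_series`.
#' @export
read_site_csv <- function(path, site_id = NULL, biome = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(SITE_CSV_COLUMNS), names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(as.character(df$TIMESTAMP), format = "%Y%m%d")
  bad <- is.na(dates) | !is.finite(df$GPP_DT_VUT_MEAN) |
    df$GPP_DT_VUT_MEAN < -5 | df$GPP_DT_VUT_MEAN > 60 |
    !is.finite(df$SW_IN) | df$SW_IN < 0 | df$SW_IN > 500 |
    !is.finite(df$TA) | df$TA < -70 | df$TA > 60 |
    !is.finite(df$SWC) | df$SWC < 0 | df$SWC > 100 |
    !is.finite(df$VPD) | df$VPD < 0 | df$VPD > 120 |
    !is.finite(df$CO2) | df$CO2 < 250 | df$CO2 > 1200 |
    !is.finite(df$GPP_QC) | df$GPP_QC < 0 | df$GPP_QC > 1
  if (any(bad)) {
    warning("dropping ", sum(bad), " unparseable/out-of-range row(s): lines ",
            paste(utils::head(which(bad) + 1L, 20), collapse = ", "))
    df <- df[!bad, ]
    dates <- dates[!bad]
  }
  out <- data.frame(
    site_id = if ("SITE_ID" %in% names(df)) df$SITE_ID
              else site_id %||% tools::file_path_sans_ext(basename(path)),
    biome = if ("BIOME" %in% names(df)) df$BIOME else biome %||% NA_character_,
    date = dates, gpp_obs = pmax(df$GPP_DT_VUT_MEAN, 0),
    quality_flag = df$GPP_QC, par = shortwave_to_par(df$SW_IN),
    t_air = df$TA, swc = df$SWC, vpd = df$VPD, co2 = df$CO2)
  if ("NDVI" %in% names(df)) out$ndvi <- df$NDVI
  site_daily_series(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a daily site record to CSV
#'
#' Inverse of [read_site_csv()] (shortwave is recovered from PAR).
#'
#' @param series A `site_daily_series`.
#' @param path Output path.
#' @export
write_site_csv <- function(series, path) {
  df <- data.frame(
    TIMESTAMP = as.integer(format(series$date, "%Y%m%d")),
    GPP_DT_VUT_MEAN = series$gpp_obs, GPP_QC = series$quality_flag,
    SW_IN = series$par / 0.46, TA = series$t_air, SWC = series$swc,
    VPD = series$vpd, CO2 = series$co2, SITE_ID = series$site_id,
    BIOME = series$biome)
  if ("ndvi" %in% names(series)) df$NDVI <- series$ndvi
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a semi-monthly NDVI series (CSV)
#'
#' Columns `year`, `month`, `half`, `ndvi` (NA = missing composite).
#'
#' @param path CSV path.
#' @return An [ndvi_series()].
#' @export
read_ndvi_csv <- function(path) {
  df <- utils::read.csv(path)
  ndvi_series(df$year, df$month, df$half, df$ndvi)
}

#' @rdname read_ndvi_csv
#' @param series An `ndvi_series`.
#' @export
write_ndvi_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("year", "month", "half", "ndvi")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' The text grid format: two header comment lines `# variable: <name>` and
#' `# units: <units>` followed by a CSV table `lat,lon,time,value` (`time`
#' ISO dates, or empty for static fields). Latitude orientation is
#' normalized (descending) on load; a missing units line is an error — no
#' silent unit guessing.
#'
#' @param path File path.
#' @param variable Optional expected variable name; mismatch is an error
#'   that lists what the file provides.
#' @return A `gridded_field`.
#' @export
read_grid_csv <- function(path, variable = NULL) {
  hdr <- readLines(path, n = 2)
  var_line <- grep("^# variable:", hdr, value = TRUE)
  unit_line <- grep("^# units:", hdr, value = TRUE)
  if (!length(unit_line))
    stop("no '# units:' header in ", path, "; units are required")
  units <- trimws(sub("^# units:", "", unit_line))
  varname <- if (length(var_line)) trimws(sub("^# variable:", "", var_line))
             else NA_character_
  if (!is.null(variable) && !identical(variable, varname))
    stop("variable '", variable, "' not found; file provides: ", varname)
  df <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(df$lat), decreasing = TRUE)
  lon <- sort(unique(df$lon))
  has_time <- "time" %in% names(df) && !all(is.na(df$time) | df$time == "")
  tm <- if (has_time) sort(unique(as.Date(df$time))) else NULL
  nt <- if (has_time) length(tm) else 1L
  arr <- array(NA_real_, c(length(lat), length(lon), nt))
  i <- match(df$lat, lat)
  j <- match(df$lon, lon)
  k <- if (has_time) match(as.Date(df$time), tm) else 1L
  arr[cbind(i, j, k)] <- df$value
  gridded_field(arr, lat, lon, time = tm, units = units)
}

#' @rdname read_grid_csv
#' @param field A `gridded_field`.
#' @export
write_grid_csv <- function(field, path, variable = "value") {
  nt <- dim(field$values)[3]
  grid <- expand.grid(lat = field$lat, lon = field$lon,
                      k = seq_len(nt))
  df <- data.frame(lat = grid$lat, lon = grid$lon,
                   time = if (!is.null(field$time))
                     as.character(field$time[grid$k]) else "",
                   value = sprintf("%.17g", as.vector(field$values)))
  df$value[df$value == "NA"] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# variable:", variable),
               paste("# units:", field$units)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

curve_to_list <- function(curve) {
  if (is.null(curve)) return(NULL)
  if (inherits(curve, "logistic_curve"))
    list(type = "logistic", a_max = curve$a_max, k = curve$k,
         x_mid = curve$x_mid)
  else list(type = "gaussian", a_max = curve$a_max, b_mid = curve$b_mid,
            b_sigma = curve$b_sigma)
}

curve_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (x$type == "logistic") logistic_curve(x$a_max, x$k, x$x_mid)
  else gaussian_curve(x$a_max, x$b_mid, x$b_sigma)
}

#' Serialize a calibrated biome model to versioned JSON
#'
#' @param model A `biome_model`.
#' @param path Output path.
#' @export
write_biome_model <- function(model, path) {
  doc <- list(
    format = "lrfgpp-biome-model", version = 1L,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("lrfgpp")),
    biome = model$biome,
    fopt_curve = curve_to_list(model$fopt_curve),
    alpha_curve = curve_to_list(model$alpha_curve),
    alpha_limit = model$alpha_limit,
    constraints = lapply(model$constraints, function(cs)
      list(variable = cs$variable, mode = cs$mode,
           curve = curve_to_list(cs$curve))),
    selected_percentiles = model$selected_percentiles,
    uncertainty = as.list(model$uncertainty))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a biome model from JSON
#'
#' @param path JSON path written by [write_biome_model()].
#' @return A `biome_model`.
#' @export
read_biome_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "lrfgpp-biome-model"))
    stop(path, " is not a biome model document")
  sp <- doc$selected_percentiles
  sp$fopt <- as.numeric(sp$fopt); sp$alpha <- as.numeric(sp$alpha)
  sp$scalars <- lapply(sp$scalars, as.numeric)
  biome_model(
    biome = doc$biome,
    fopt_curve = curve_from_list(doc$fopt_curve),
    alpha_curve = curve_from_list(doc$alpha_curve),
    alpha_limit = if (!is.null(doc$alpha_limit))
      as.numeric(doc$alpha_limit),
    constraints = lapply(doc$constraints, function(cs)
      constraint_spec(cs$variable, cs$mode, curve_from_list(cs$curve))),
    selected_percentiles = sp,
    uncertainty = unlist(doc$uncertainty))
}

#' Default run configuration
#'
#' All defaults mirror the model's standard settings: PAR fraction 0.46,
#' alpha cap 0.25, low-light threshold 25 W m-2, quality threshold 0.5,
#' 20 NDVI bins, driver bin widths (T_air 5 degC, SWC 5 %Vol, VPD 25 hPa,
#' CO2 5 ppm), percentile grid stride 5 and 200 bootstrap iterations.
#'
#' @return A named list (config version 1).
#' @export
default_run_config <- function() {
  list(config_version = 1L,
       seed = 1L,
       quality_threshold = 0.5,
       fopt_level = 95, low_light_par = 25, alpha_cap = 0.25,
       n_ndvi_bins = 20, min_bin_count = 5,
       percentile_stride = 5,
       bootstrap_iterations = 200,
       constraint_ranking = c("t_air", "swc", "vpd"),
       include_co2 = FALSE,
       simulate = list(n_sites = 12, n_years = 3, biome = "savannah_shrublands",
                       grid = FALSE),
       paths = list(site_dir = "sites", model_file = "biome_model.json",
                    out_dir = "out"))
}

#' Read a run configuration (YAML)
#'
#' Missing keys fall back to [default_run_config()]; an unknown
#' `config_version` is an error.
#'
#' @param path YAML file path.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$config_version) && cfg$config_version != 1L)
    stop("unsupported config_version: ", cfg$config_version)
  merge_lists(default_run_config(), cfg)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
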
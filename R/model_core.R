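#' Light response parameters
#'
#' Container for the two parameters of the asymptotic (Mitscherlich) light
#' response function: photosynthetic capacity `fopt` (the GPP asymptote at
#' light saturation, g C m-2 day-1) and quantum efficiency `alpha` (the
#' initial slope of the light response curve, g C day-1 W-1 of PAR).
#'
#' `alpha` is capped at 0.25 g C day-1 W-1: larger values are physically
#' unrealistic at ecosystem scale and are rejected at construction.
#'
#' @param fopt Photosynthetic capacity, g C m-2 day-1; must be > 0.
#' @param alpha Quantum efficiency, g C day-1 W-1; must be in (0, 0.25].
#' @return An object of class `light_response_params`.
#' @export
light_response_params <- function(fopt, alpha) {
  stopifnot(is.numeric(fopt), is.numeric(alpha), length(fopt) == length(alpha))
  if (any(!is.finite(fopt)) || any(fopt <= 0))
    stop("fopt must be finite and > 0")
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha > 0.25))
    stop("alpha must be in (0, 0.25]")
  structure(list(fopt = fopt, alpha = alpha), class = "light_response_params")
}

#' Three-parameter logistic response curve
#'
#' `a_max / (1 + exp(-k * (x - x_mid)))`: `a_max` is the upper asymptote (in
#' units of the response), `k` the steepness (per unit of x) and `x_mid` the
#' midpoint, where the response equals `a_max / 2`. Used both for the
#' NDVI couplings of F_opt and alpha and for logistic environmental
#' constraints (air temperature, VPD), where `k` may be negative for a
#' decreasing response.
#'
#' @param a_max Curve maximum; must be > 0.
#' @param k Steepness; finite and nonzero.
#' @param x_mid Midpoint, units of x.
#' @return An object of class `logistic_curve`.
#' @export
logistic_curve <- function(a_max, k, x_mid) {
  stopifnot(length(a_max) == 1, length(k) == 1, length(x_mid) == 1)
  if (!is.finite(a_max) || a_max <= 0) stop("a_max must be finite and > 0")
  if (!is.finite(k) || k == 0) stop("k must be finite and nonzero")
  if (!is.finite(x_mid)) stop("x_mid must be finite")
  structure(list(a_max = a_max, k = k, x_mid = x_mid),
            class = c("logistic_curve", "response_curve"))
}

#' Gaussian (bell-shaped) response curve
#'
#' `a_max * exp(-(x - b_mid)^2 / (2 * b_sigma^2))`: peak value `a_max` at
#' centre `b_mid`, with width `b_sigma` (the standard deviation of the
#' response). Used for the soil-water-content constraint, which suppresses
#' GPP at both the dry (drought stress) and wet (waterlogging) ends.
#'
#' @param a_max Peak value; > 0.
#' @param b_mid Centre position, units of x.
#' @param b_sigma Width (standard deviation), units of x; > 0.
#' @return An object of class `gaussian_curve`.
#' @export
gaussian_curve <- function(a_max, b_mid, b_sigma) {
  stopifnot(length(a_max) == 1, length(b_mid) == 1, length(b_sigma) == 1)
  if (!is.finite(a_max) || a_max <= 0) stop("a_max must be finite and > 0")
  if (!is.finite(b_mid)) stop("b_mid must be finite")
  if (!is.finite(b_sigma) || b_sigma <= 0) stop("b_sigma must be finite and > 0")
  structure(list(a_max = a_max, b_mid = b_mid, b_sigma = b_sigma),
            class = c("gaussian_curve", "response_curve"))
}

#' Environmental constraint specification
#'
#' Binds a fitted response curve to a driver variable and a mode. In
#' `scalar` mode the (normalized) response multiplies modelled GPP and is
#' clipped to \[0, 1\]; in `upper_boundary` mode the response is a ceiling
#' (g C m-2 day-1) that modelled GPP cannot exceed.
#'
#' @param variable One of `"t_air"`, `"swc"`, `"vpd"`, `"co2"`.
#' @param mode `"scalar"` or `"upper_boundary"`.
#' @param curve A `logistic_curve` or `gaussian_curve`.
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(variable, mode, curve) {
  variable <- match.arg(variable, c("t_air", "swc", "vpd", "co2"))
  mode <- match.arg(mode, c("scalar", "upper_boundary"))
  if (!inherits(curve, "response_curve"))
    stop("curve must be a logistic_curve or gaussian_curve")
  structure(list(variable = variable, mode = mode, curve = curve),
            class = "constraint_spec")
}

#' Convert downwelling shortwave radiation to PAR
#'
#' Photosynthetically active radiation is taken as 46% of downwelling
#' shortwave radiation.
#'
#' @param sw_down Downwelling shortwave radiation, W m-2; must be >= 0.
#' @return PAR in W m-2.
#' @export
shortwave_to_par <- function(sw_down) {
  if (any(sw_down < 0, na.rm = TRUE)) stop("sw_down must be >= 0")
  0.46 * sw_down
}

#' Asymptotic light response function for GPP
#'
#' GPP = F_opt * (1 - exp(-alpha * PAR / F_opt)). GPP is reported with a
#' positive sign for uptake. The function is monotone nondecreasing and
#' concave in PAR, with initial slope alpha and asymptote F_opt.
#'
#' @param fopt Photosynthetic capacity, g C m-2 day-1 (vectorized), or a
#'   `light_response_params` object (then `alpha` must be missing).
#' @param alpha Quantum efficiency, g C day-1 W-1 (vectorized).
#' @param par Incoming PAR, W m-2; must be >= 0.
#' @return GPP in g C m-2 day-1.
#' @export
lrf_gpp <- function(fopt, alpha, par) {
  if (inherits(fopt, "light_response_params")) {
    if (missing(par)) { par <- alpha } # lrf_gpp(params, par)
    alpha <- fopt$alpha
    fopt <- fopt$fopt
  }
  if (any(par < 0, na.rm = TRUE)) stop("par must be >= 0")
  fopt * (1 - exp(-alpha * par / fopt))
}

#' Evaluate a logistic response curve
#'
#' @param curve A `logistic_curve`.
#' @param x Driver values.
#' @return Response values, bounded in (0, a_max).
#' @export
logistic_response <- function(curve, x) {
  stopifnot(inherits(curve, "logistic_curve"))
  curve$a_max / (1 + exp(-curve$k * (x - curve$x_mid)))
}

#' Evaluate a Gaussian response curve
#'
#' @param curve A `gaussian_curve`.
#' @param x Driver values.
#' @return Response values, equal to a_max at x = b_mid.
#' @export
gaussian_response <- function(curve, x) {
  stopifnot(inherits(curve, "gaussian_curve"))
  curve$a_max * exp(-(x - curve$b_mid)^2 / (2 * curve$b_sigma^2))
}

#' Evaluate any response curve
#'
#' Dispatches to [logistic_response()] or [gaussian_response()].
#'
#' @param curve A `logistic_curve` or `gaussian_curve`.
#' @param x Driver values.
#' @return Response values.
#' @export
curve_response <- function(curve, x) {
  if (inherits(curve, "logistic_curve")) return(logistic_response(curve, x))
  if (inherits(curve, "gaussian_curve")) return(gaussian_response(curve, x))
  stop("unknown curve class")
}

#' Apply environmental scalars and upper boundaries to modelled GPP
#'
#' Scalars can only decrease GPP: each scalar is clipped at one before
#' multiplying. Upper boundaries are ceilings (g C m-2 day-1) applied after
#' the scalars. The result never exceeds the unconstrained input.
#'
#' @param gpp_raw Unconstrained GPP, g C m-2 day-1, >= 0 (vectorized).
#' @param scalars List of scalar values (each a vector recyclable against
#'   `gpp_raw`); all must be >= 0.
#' @param boundaries List (or vector) of GPP ceilings, recyclable likewise.
#' @return Constrained GPP.
#' @export
constrain_gpp <- function(gpp_raw, scalars = list(), boundaries = list()) {
  if (any(gpp_raw < 0, na.rm = TRUE)) stop("gpp_raw must be >= 0")
  out <- gpp_raw
  for (s in scalars) {
    if (any(s < 0, na.rm = TRUE)) stop("scalars must be >= 0")
    out <- out * pmin(s, 1)
  }
  if (is.numeric(boundaries)) boundaries <- list(boundaries)
  for (b in boundaries) out <- pmin(out, b)
  out
}

#' Saturation vapour pressure (Magnus formula)
#'
#' @param t_air Air temperature, degrees C.
#' @return Saturation vapour pressure, hPa.
#' @export
esat_magnus <- function(t_air) {
  6.112 * exp(17.62 * t_air / (243.12 + t_air))
}

#' Vapour pressure deficit from temperature and actual vapour pressure
#'
#' VPD = e_sat(T) - e_actual with the Magnus saturation curve, floored at
#' zero (supersaturated air gives 0). A convenience for driver preparation;
#' VPD can alternatively be supplied directly as an input.
#'
#' @param t_air Air temperature, degrees C.
#' @param vapour_pressure Actual vapour pressure, hPa; >= 0.
#' @return VPD in hPa.
#' @export
vpd_from_temperature_humidity <- function(t_air, vapour_pressure) {
  if (any(vapour_pressure < 0, na.rm = TRUE))
    stop("vapour_pressure must be >= 0")
  pmax(esat_magnus(t_air) - vapour_pressure, 0)
}
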
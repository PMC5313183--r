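#' Coefficients of the surface fire spread-rate model
#'
#' The spread rate of a surface fire is modelled as
#' `R = R0 * Kf * Kw * Kt` (m/min), where the initial rate
#' `R0 = a*T + b*v + c*(1 - h) - d` depends on daily maximum temperature `T`
#' (degC), wind speed `v` (m/s) and relative humidity fraction `h`;
#' `Kw = exp(wind_coef * v)` is the wind multiplier,
#' `Kt = exp(slope_coef * tan(phi)^slope_exp)` the (upslope) terrain
#' multiplier and `Kf` a fuel-type multiplier constrained to \[0.8, 1.8\].
#' Defaults are the coefficients calibrated on Chinese forest fires:
#' `a = 0.03`, `b = 0.05`, `c = 0.01`, `d = 0.3`, `wind_coef = 0.1783`,
#' `slope_coef = 3.533`, `slope_exp = 1.2`. The default `Kf` ordering puts
#' pine above fir above others above broadleaf, matching their relative
#' flammability in subtropical coniferous systems.
#'
#' @param a,b,c,d Coefficients of `R0` (per degC, per m/s, dimensionless,
#'   constant; all in m/min).
#' @param wind_coef Wind-exponent coefficient (s/m).
#' @param slope_coef,slope_exp Slope-exponent coefficient and exponent.
#' @param kf Named fuel multipliers for `pine`, `fir`, `broadleaf`,
#'   `others`; each must lie in \[0.8, 1.8\].
#' @return An object of class `spread_params`.
#' @export
spread_params <- function(a = 0.03, b = 0.05, c = 0.01, d = 0.3,
                          wind_coef = 0.1783,
                          slope_coef = 3.533, slope_exp = 1.2,
                          kf = c(pine = 1.2, fir = 1.0,
                                 broadleaf = 0.8, others = 0.9)) {
  vals <- c(a = a, b = b, c = c, d = d, wind_coef = wind_coef,
            slope_coef = slope_coef, slope_exp = slope_exp, kf)
  if (any(!is.finite(vals))) stop("all spread parameters must be finite")
  need <- c("pine", "fir", "broadleaf", "others")
  if (!all(need %in% names(kf)))
    stop("kf must name all of: ", paste(need, collapse = ", "))
  if (any(kf < 0.8 | kf > 1.8)) stop("fuel multipliers must lie in [0.8, 1.8]")
  structure(list(a = a, b = b, c = c, d = d, wind_coef = wind_coef,
                 slope_coef = slope_coef, slope_exp = slope_exp,
                 kf = kf[need]),
            class = "spread_params")
}

#' @export
print.spread_params <- function(x, ...) {
  cat("Spread-rate model R = R0 * Kf * Kw * Kt\n")
  cat(sprintf("  R0 = %g*T + %g*v + %g*(1-h) - %g  (m/min, clamped at 0)\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  Kw = exp(%g*v); Kt = exp(%g*tan(phi)^%g)\n",
              x$wind_coef, x$slope_coef, x$slope_exp))
  cat("  Kf:", paste(sprintf("%s=%g", names(x$kf), x$kf), collapse = ", "), "\n")
  invisible(x)
}

#' Fire spread rate and its components
#'
#' Vectorised over all numeric inputs. Relative humidity is accepted in
#' percent and converted to a fraction; a negative `R0` is clamped to zero
#' (no spread). The slope multiplier uses the upslope angle only; pass
#' `phi = 0` for flat or downslope spread.
#'
#' @param t_max Daily maximum temperature (degC).
#' @param wind Wind speed (m/s).
#' @param rh Relative humidity in percent (0--100).
#' @param phi Slope angle in degrees, `0 <= phi < 90`.
#' @param fuel_class Character vector over `pine`, `fir`, `broadleaf`,
#'   `others`.
#' @param params A [spread_params()].
#' @return List with vectors `R`, `R0`, `Kw`, `Kt`, `Kf` (m/min and
#'   dimensionless multipliers).
#' @export
spread_rate <- function(t_max, wind, rh, phi, fuel_class,
                        params = spread_params()) {
  if (any(phi >= 90) || any(phi < 0))
    stop("slope angle must lie in [0, 90) degrees")
  if (any(rh < 0 | rh > 100)) stop("rh must be a percentage in [0, 100]")
  h <- rh / 100
  r0 <- pmax(0, params$a * t_max + params$b * wind +
               params$c * (1 - h) - params$d)
  kw <- exp(params$wind_coef * wind)
  kt <- exp(params$slope_coef * tan(phi * pi / 180)^params$slope_exp)
  kf <- unname(params$kf[fuel_class])
  if (any(is.na(kf))) stop("unknown fuel class")
  list(R = r0 * kf * kw * kt, R0 = r0, Kw = kw, Kt = kt, Kf = kf)
}
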
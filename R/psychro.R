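# Moist-air conversions shared by every index evaluator.  The saturation
# vapour pressure formula is isolated here so an alternative fit (e.g.
# Bolton 1980) could be swapped in one place; all golden values in the test
# suite derive from this same formula.

# Buck (1981) curve ew4 over liquid water, result in kPa.
.esat_buck <- function(t_c) {
  0.61121 * exp(17.502 * t_c / (240.97 + t_c))
}

#' Saturation vapour pressure over liquid water
#'
#' Buck (1981) fit, valid for the meteorological range considered here.
#'
#' @param t_c Air temperature, degrees C, in \[-40, 60\].
#' @return Saturation vapour pressure, kPa.
#' @examples
#' saturation_vapour_pressure(0)   # ~0.611 kPa
#' saturation_vapour_pressure(20)  # ~2.34 kPa
#' @export
saturation_vapour_pressure <- function(t_c) {
  if (any(!is.finite(t_c) | t_c < -40 | t_c > 60))
    stop("temperature outside [-40, 60] degC", call. = FALSE)
  .esat_buck(t_c)
}

#' Vapour pressure from temperature and relative humidity
#'
#' @param t_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent (0-100).
#' @return Vapour pressure, kPa.
#' @export
vapour_pressure <- function(t_c, rh_pct) {
  if (any(!is.finite(rh_pct) | rh_pct < 0 | rh_pct > 100))
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  (rh_pct / 100) * saturation_vapour_pressure(t_c)
}

#' Specific humidity from temperature, relative humidity and pressure
#'
#' Mass of water vapour per unit mass of moist air,
#' q = 0.622 e / (p - 0.378 e).
#'
#' @param t_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent.
#' @param p_kpa Pressure, kPa.
#' @return Specific humidity, kg/kg.
#' @seealso [rh_from_specific_humidity()] for the inverse.
#' @export
specific_humidity <- function(t_c, rh_pct, p_kpa = 101.325) {
  e <- vapour_pressure(t_c, rh_pct)
  if (any(e >= p_kpa))
    stop("vapour pressure exceeds total pressure", call. = FALSE)
  0.622 * e / (p_kpa - 0.378 * e)
}

#' Relative humidity from specific humidity
#'
#' Exact inverse of [specific_humidity()] at the same temperature and
#' pressure.  A specific humidity implying relative humidity above 100 %
#' (supersaturation with respect to the temperature supplied) is an error,
#' never silently clipped.
#'
#' @param q Specific humidity, kg/kg, non-negative.
#' @param t_c Air temperature, degrees C.
#' @param p_kpa Pressure, kPa.
#' @return Relative humidity, percent.
#' @export
rh_from_specific_humidity <- function(q, t_c, p_kpa = 101.325) {
  if (any(!is.finite(q) | q < 0))
    stop("specific humidity must be non-negative", call. = FALSE)
  e <- q * p_kpa / (0.622 + 0.378 * q)
  rh <- 100 * e / saturation_vapour_pressure(t_c)
  if (any(rh > 100 + 1e-9))
    stop("supersaturation: implied relative humidity exceeds 100 %",
         call. = FALSE)
  pmin(rh, 100)
}

#' Dewpoint temperature
#'
#' Closed-form inversion of the Buck saturation curve at the ambient vapour
#' pressure.  Undefined at zero humidity.
#'
#' @param t_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent, strictly positive.
#' @return Dewpoint temperature, degrees C; equals `t_c` at saturation.
#' @export
dewpoint <- function(t_c, rh_pct) {
  if (any(rh_pct <= 0))
    stop("dewpoint is undefined at zero humidity", call. = FALSE)
  e <- vapour_pressure(t_c, rh_pct)
  s <- log(e / 0.61121)
  240.97 * s / (17.502 - s)
}

# Mixing ratio (kg water per kg dry air) from vapour pressure.
.mixing_ratio <- function(e_kpa, p_kpa) {
  0.622 * e_kpa / (p_kpa - e_kpa)
}
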
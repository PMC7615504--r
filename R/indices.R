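# The remaining heat stress indices, each a pure vectorised mapping from an
# air_state to an index_value.  Unit dialects (all fixed here, once):
#   - heat index: NOAA Rothfusz regression in degF with the low/high-RH
#     adjustments and the simple-average branch below 80 degF;
#   - humidex: Meteorological Service of Canada form, dewpoint-derived
#     vapour pressure in hPa;
#   - apparent temperature: Steadman's shaded form with wind, e in hPa;
#   - sWBGT: Australian Bureau dialect, e in hPa;
#   - WBGT-indoor: Bernard combination of psychrometric wet-bulb and air
#     temperature with a log10(wind) correction.

#' NOAA heat index
#'
#' Rothfusz regression with the official low-humidity and high-humidity
#' adjustment terms.  Below the 80 degF threshold NOAA's simple
#' average-with-temperature formula is used (note: this is close to, but
#' not exactly, the air temperature).  Input and output in degrees C.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C; total on valid states.
#' @export
hsi_heat_index <- function(state) {
  state <- as_air_state(state)
  tf <- state$t_c * 9 / 5 + 32
  rh <- state$rh_pct
  simple <- 0.5 * (tf + 61 + (tf - 68) * 1.2 + rh * 0.094)
  hi <- simple
  reg <- simple >= 80
  if (any(reg)) {
    t <- tf[reg]; r <- rh[reg]
    h <- -42.379 + 2.04901523 * t + 10.14333127 * r -
      0.22475541 * t * r - 6.83783e-3 * t^2 - 5.481717e-2 * r^2 +
      1.22874e-3 * t^2 * r + 8.5282e-4 * t * r^2 - 1.99e-6 * t^2 * r^2
    lowrh <- r < 13 & t >= 80 & t <= 112
    h[lowrh] <- h[lowrh] - ((13 - r[lowrh]) / 4) *
      sqrt((17 - abs(t[lowrh] - 95)) / 17)
    highrh <- r > 85 & t >= 80 & t <= 87
    h[highrh] <- h[highrh] + ((r[highrh] - 85) / 10) * ((87 - t[highrh]) / 5)
    hi[reg] <- h
  }
  index_value((hi - 32) * 5 / 9)
}

#' Humidex
#'
#' Air temperature plus 0.5555 times the excess of the dewpoint-derived
#' vapour pressure (hPa) over 10 hPa.  Undefined at zero humidity because
#' the dewpoint is.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C.
#' @export
hsi_humidex <- function(state) {
  state <- as_air_state(state)
  reason <- ifelse(state$rh_pct <= 0, "RH_ZERO", NA_character_)
  value <- rep(NA_real_, nrow(state))
  ok <- is.na(reason)
  if (any(ok)) {
    td_k <- dewpoint(state$t_c[ok], state$rh_pct[ok]) + 273.15
    e_hpa <- 6.11 * exp(5417.7530 * (1 / 273.16 - 1 / td_k))
    value[ok] <- state$t_c[ok] + 0.5555 * (e_hpa - 10)
  }
  index_value(value, reason)
}

#' Apparent temperature (Steadman, shaded)
#'
#' AT = Ta + 0.33 e - 0.70 v - 4.00, with e the vapour pressure in hPa and
#' v the 10 m wind in m/s; the shaded form includes wind but no radiation.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C.
#' @export
hsi_apparent_temperature <- function(state) {
  state <- as_air_state(state)
  e_hpa <- 10 * vapour_pressure(state$t_c, state$rh_pct)
  index_value(state$t_c + 0.33 * e_hpa - 0.70 * state$wind_ms - 4.00)
}

#' Simplified WBGT
#'
#' sWBGT = 0.567 Ta + 0.393 e + 3.94 with e in hPa.  A crude stand-in for
#' full WBGT at moderately high wind and radiation, but widely used.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C.
#' @export
hsi_swbgt <- function(state) {
  state <- as_air_state(state)
  e_hpa <- 10 * vapour_pressure(state$t_c, state$rh_pct)
  index_value(0.567 * state$t_c + 0.393 * e_hpa + 3.94)
}

#' Indoor wet-bulb globe temperature
#'
#' WBGT without the black-globe radiation term:
#' 0.67 Twb + 0.33 Ta - 0.048 log10(v) (Ta - Twb), with Twb the
#' Davies-Jones wet-bulb and v the package wind assumption (0.5 m/s by
#' default).  A convex combination of Twb and Ta for ordinary winds.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C; wet-bulb convergence failures
#'   propagate.
#' @export
hsi_wbgt_indoor <- function(state) {
  state <- as_air_state(state)
  wb <- hsi_wbt(state)
  value <- 0.67 * wb$value + 0.33 * state$t_c -
    0.048 * log10(state$wind_ms) * (state$t_c - wb$value)
  index_value(value, wb$reason)
}

#' Mora-derived Ts metric
#'
#' Ts = WBT + 4.5 (1 - f^2) with f the fractional relative humidity
#' (rh/100): the wet-bulb plus a dryness bonus of up to 4.5 degrees C that
#' vanishes at saturation.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C.
#' @export
hsi_ts_mora <- function(state) {
  state <- as_air_state(state)
  wb <- hsi_wbt(state)
  f <- state$rh_pct / 100
  index_value(wb$value + 4.5 * (1 - f^2), wb$reason)
}

#' Registry of heat stress index evaluators
#'
#' Maps the stable index identifiers used in CSV headers and run configs to
#' evaluator functions.  Lookup is case-insensitive.
#'
#' @return Named list of evaluators: `WBT`, `HI`, `HUMIDEX`, `AT`, `UTCI`,
#'   `WBGT_INDOOR`, `SWBGT`, `TS_MORA`.
#' @examples
#' names(hsi_registry())
#' hsi_index("utci")(air_state(25, 40))
#' @export
hsi_registry <- function() {
  list(WBT = hsi_wbt,
       HI = hsi_heat_index,
       HUMIDEX = hsi_humidex,
       AT = hsi_apparent_temperature,
       UTCI = hsi_utci,
       WBGT_INDOOR = hsi_wbgt_indoor,
       SWBGT = hsi_swbgt,
       TS_MORA = hsi_ts_mora)
}

#' @rdname hsi_registry
#' @param name Index identifier, case-insensitive.
#' @export
hsi_index <- function(name) {
  reg <- hsi_registry()
  key <- toupper(trimws(name))
  if (!key %in% names(reg))
    stop("unknown index '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[key]]
}
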
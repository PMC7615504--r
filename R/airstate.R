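#' Construct a set of atmospheric states
#'
#' An `air_state` is a data frame of moist-air conditions: dry-bulb
#' temperature, relative humidity, 10 m wind speed, mean radiant temperature
#' and station pressure.  All index evaluators in the package accept an
#' `air_state` and are vectorised over its rows.
#'
#' The defaults encode the fixed assumptions used throughout the package for
#' index intercomparison: wind of 0.5 m/s (the lowest reference wind for
#' which the UTCI polynomial was fitted) and mean radiant temperature equal
#' to air temperature (reasonable for shaded/indoor conditions).  Pressure
#' defaults to one standard atmosphere; it matters only for wet-bulb
#' temperature and specific-humidity conversions.
#'
#' @param t_c Dry-bulb air temperature, degrees C.
#' @param rh_pct Relative humidity, percent on the 0-100 scale.
#' @param wind_ms 10 m wind speed, m/s; must be positive.  Default 0.5.
#' @param tmrt_c Mean radiant temperature, degrees C.  Defaults to `t_c`.
#' @param p_kpa Station pressure, kPa; must be positive.  Default 101.325.
#' @return A data frame of class `air_state` with columns `t_c`, `rh_pct`,
#'   `wind_ms`, `tmrt_c`, `p_kpa`.  Scalar arguments are recycled to the
#'   longest length.
#' @examples
#' air_state(30, 50)
#' air_state(t_c = c(20, 35, 40), rh_pct = c(50, 80, 20))
#' @export
air_state <- function(t_c, rh_pct, wind_ms = 0.5, tmrt_c = t_c,
                      p_kpa = 101.325) {
  n <- max(length(t_c), length(rh_pct), length(wind_ms), length(tmrt_c),
           length(p_kpa))
  if (n == 0L) stop("air_state needs at least one condition", call. = FALSE)
  t_c <- rep_len(as.numeric(t_c), n)
  rh_pct <- rep_len(as.numeric(rh_pct), n)
  wind_ms <- rep_len(as.numeric(wind_ms), n)
  tmrt_c <- rep_len(as.numeric(tmrt_c), n)
  p_kpa <- rep_len(as.numeric(p_kpa), n)
  if (any(!is.finite(t_c)) || any(!is.finite(rh_pct)))
    stop("temperature and relative humidity must be finite", call. = FALSE)
  if (any(rh_pct < 0 | rh_pct > 100))
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  if (any(!is.finite(wind_ms) | wind_ms <= 0))
    stop("wind speed must be positive", call. = FALSE)
  if (any(!is.finite(p_kpa) | p_kpa <= 0))
    stop("pressure must be positive", call. = FALSE)
  out <- data.frame(t_c = t_c, rh_pct = rh_pct, wind_ms = wind_ms,
                    tmrt_c = tmrt_c, p_kpa = p_kpa)
  class(out) <- c("air_state", "data.frame")
  out
}

#' @export
print.air_state <- function(x, ...) {
  cat("<air_state> ", nrow(x), " condition(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# Coerce plain data frames with the right columns; used by run_* commands.
as_air_state <- function(x) {
  if (inherits(x, "air_state")) return(x)
  stopifnot(all(c("t_c", "rh_pct") %in% names(x)))
  air_state(t_c = x$t_c, rh_pct = x$rh_pct,
            wind_ms = if ("wind_ms" %in% names(x)) x$wind_ms else 0.5,
            tmrt_c = if ("tmrt_c" %in% names(x)) x$tmrt_c else x$t_c,
            p_kpa = if ("p_kpa" %in% names(x)) x$p_kpa else 101.325)
}

#' Construct an index-value container
#'
#' Every index evaluator returns an `index_value`: a data frame with the
#' numeric value, a `defined` flag and a machine-readable `reason` code for
#' undefined entries (e.g. `VP_LIMIT`, `T_LIMIT` for UTCI validity
#' violations).  Undefined entries carry `NA` values; defined entries are
#' finite.
#'
#' @param value Numeric vector of index values, degrees C scale.
#' @param reason Character vector of reason codes, `NA` where the value is
#'   defined.  Recycled.
#' @return Data frame of class `index_value` with columns `value`,
#'   `defined`, `reason`.
#' @export
index_value <- function(value, reason = NA_character_) {
  n <- max(length(value), length(reason))
  value <- rep_len(as.numeric(value), n)
  reason <- rep_len(as.character(reason), n)
  defined <- is.na(reason) & is.finite(value)
  value[!defined] <- NA_real_
  reason[!defined & is.na(reason)] <- "NONFINITE"
  out <- data.frame(value = value, defined = defined, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("index_value", "data.frame")
  out
}

#' @export
print.index_value <- function(x, ...) {
  cat("<index_value> ", sum(x$defined), "/", nrow(x), " defined\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
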
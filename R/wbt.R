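# Thermodynamic wet-bulb temperature after Davies-Jones (2008): the
# wet-bulb is recovered by inverting the equivalent potential temperature,
# i.e. finding the temperature at which a saturated parcel at the same
# pressure has the same theta-e as the actual parcel.  theta-e itself uses
# Bolton's (1980) pseudoadiabatic formula (his eq. 39), which Davies-Jones
# takes as the most accurate closed form.

# Bolton LCL temperature (K), eq. 21, from temperature and vapour pressure.
.t_lcl <- function(t_k, e_hpa) {
  2840 / (3.5 * log(t_k) - log(e_hpa) - 4.805) + 55
}

# Equivalent potential temperature (K).  t_c in degC, e_kpa vapour
# pressure, p_kpa total pressure.  For a saturated parcel pass
# e_kpa = esat(t_c) (the LCL is then the parcel itself).
.theta_e <- function(t_c, e_kpa, p_kpa, saturated = FALSE) {
  t_k <- t_c + 273.15
  p_hpa <- p_kpa * 10
  e_hpa <- e_kpa * 10
  r <- 1000 * .mixing_ratio(e_kpa, p_kpa)  # g/kg
  tl <- if (saturated) t_k else ifelse(e_hpa > 0, .t_lcl(t_k, e_hpa), t_k)
  pot <- t_k * (1000 / p_hpa)^(0.2854 * (1 - 0.28e-3 * r))
  pot * exp((3.376 / tl - 0.00254) * r * (1 + 0.81e-3 * r))
}

# Saturated theta-e as a function of candidate wet-bulb temperature;
# strictly increasing, which makes bisection safe.
.theta_e_sat <- function(tw_c, p_kpa) {
  .theta_e(tw_c, .esat_buck(tw_c), p_kpa, saturated = TRUE)
}

# Vectorised bisection for the wet-bulb.  The root is bracketed by
# [-85 degC, t_c]: a saturated parcel at t_c has theta-e >= that of the
# subsaturated parcel, and theta-e-sat collapses towards the dry adiabat
# at very cold temperatures.  60 halvings take the bracket far below the
# 0.01 degC tolerance.
.wbt_davies_jones <- function(t_c, rh_pct, p_kpa, tol = 0.01,
                              max_iter = 100L) {
  # Bolton's LCL approximation can leave the parcel theta-e marginally
  # above the saturated curve at the dry-bulb itself, so the upper bracket
  # sits slightly above t_c and the result is clamped back to t_c.
  target <- .theta_e(t_c, vapour_pressure(t_c, rh_pct), p_kpa)
  lo <- rep_len(-85, length(t_c))
  hi <- t_c + 0.1
  ok <- (.theta_e_sat(lo, p_kpa) - target) <= 0 &
        (.theta_e_sat(hi, p_kpa) - target) >= 0
  it <- 0L
  while (any(ok & (hi - lo) > tol / 4) && it < max_iter) {
    mid <- (lo + hi) / 2
    up <- .theta_e_sat(mid, p_kpa) < target
    lo <- ifelse(ok & up, mid, lo)
    hi <- ifelse(ok & !up, mid, hi)
    it <- it + 1L
  }
  value <- pmin((lo + hi) / 2, t_c)
  converged <- ok & (hi - lo) <= tol
  list(value = ifelse(converged, value, NA_real_), converged = converged)
}

#' Wet-bulb temperature (Davies-Jones)
#'
#' Thermodynamic wet-bulb temperature obtained by inverting Bolton's
#' equivalent potential temperature, following Davies-Jones (2008).
#' Converged to better than 0.01 degrees C; at saturation the wet-bulb
#' equals the dry-bulb.
#'
#' @param state An [air_state()].
#' @return An [index_value()] in degrees C.  Non-convergence (not expected
#'   in the meteorological range) is reported with reason `CONVERGENCE`.
#' @examples
#' hsi_wbt(air_state(30, 100))  # = 30
#' hsi_wbt(air_state(30, 50))
#' @export
hsi_wbt <- function(state) {
  state <- as_air_state(state)
  r <- .wbt_davies_jones(state$t_c, state$rh_pct, state$p_kpa)
  index_value(r$value,
              reason = ifelse(r$converged, NA_character_, "CONVERGENCE"))
}
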
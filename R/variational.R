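# The marginal temperature-equivalent change M = (dU/dT) / (dU/dh): the
# change in relative humidity (% RH) that moves an index as much as a 1 degC
# change in temperature, i.e. the gradient of the index's isopleth in
# temperature-humidity space.  M is unit-free across indices and so lets
# indices calibrated to completely different scales be compared at the same
# atmospheric state.  Partials are estimated by finite differences; forward
# differences are the default, a central scheme is kept as a cross-check.

#' Finite-difference scheme
#'
#' @param delta_t Temperature step, degrees C, in (0, 1]. Default 0.1,
#'   comfortably above the 0.01 degC wet-bulb solver tolerance so solver
#'   noise cannot corrupt the differences.
#' @param delta_h Relative-humidity step, percentage points, in (0, 1].
#' @param mode `"forward"` (default) or `"central"`.
#' @return List of class `fd_scheme`.
#' @export
fd_scheme <- function(delta_t = 0.1, delta_h = 0.1,
                      mode = c("forward", "central")) {
  mode <- match.arg(mode)
  if (!is.finite(delta_t) || delta_t <= 0 || delta_t > 1)
    stop("delta_t must be in (0, 1]", call. = FALSE)
  if (!is.finite(delta_h) || delta_h <= 0 || delta_h > 1)
    stop("delta_h must be in (0, 1]", call. = FALSE)
  structure(list(delta_t = delta_t, delta_h = delta_h, mode = mode),
            class = "fd_scheme")
}

# Resolve an index argument (function or registry name) to an evaluator
# plus a display name.
.resolve_index <- function(index) {
  if (is.character(index)) {
    list(fn = hsi_index(index), name = toupper(trimws(index)))
  } else if (is.function(index)) {
    list(fn = index, name = "custom")
  } else stop("index must be an evaluator function or a registry name",
              call. = FALSE)
}

# Re-evaluate an index at a displaced state.  The radiant excess
# (tmrt - t) is preserved under temperature displacement, matching the
# package-wide assumption that Tmrt tracks air temperature.
.displace <- function(state, dt = 0, dh = 0) {
  air_state(t_c = state$t_c + dt,
            rh_pct = state$rh_pct + dh,
            wind_ms = state$wind_ms,
            tmrt_c = state$tmrt_c + dt,
            p_kpa = state$p_kpa)
}

#' Finite-difference partial derivatives of an index
#'
#' `partial_t` differentiates with respect to air temperature (index units
#' per degree C), `partial_h` with respect to relative humidity (index
#' units per percentage point).  Where a forward humidity step would leave
#' the physical range (h + delta_h > 100 %), a backward step is taken and
#' flagged in the `backward` column.
#'
#' @param index An evaluator function or registry name (see
#'   [hsi_registry()]).
#' @param state An [air_state()]; vectorised over rows.
#' @param scheme An [fd_scheme()].
#' @return Data frame with columns `value`, `defined`, `reason`,
#'   `backward`.  A derivative is undefined whenever the index is undefined
#'   at any stencil point; the reason is carried over.
#' @export
partial_t <- function(index, state, scheme = fd_scheme()) {
  idx <- .resolve_index(index)
  state <- as_air_state(state)
  dt <- scheme$delta_t
  if (scheme$mode == "forward") {
    u0 <- idx$fn(state)
    u1 <- idx$fn(.displace(state, dt = dt))
    value <- (u1$value - u0$value) / dt
    reason <- ifelse(u0$defined & u1$defined, NA_character_,
                     ifelse(!u0$defined, u0$reason, u1$reason))
  } else {
    um <- idx$fn(.displace(state, dt = -dt))
    up <- idx$fn(.displace(state, dt = dt))
    value <- (up$value - um$value) / (2 * dt)
    reason <- ifelse(um$defined & up$defined, NA_character_,
                     ifelse(!um$defined, um$reason, up$reason))
  }
  out <- index_value(value, reason)
  out$backward <- FALSE
  out
}

#' @rdname partial_t
#' @export
partial_h <- function(index, state, scheme = fd_scheme()) {
  idx <- .resolve_index(index)
  state <- as_air_state(state)
  dh <- scheme$delta_h
  n <- nrow(state)
  if (scheme$mode == "forward") {
    backward <- state$rh_pct + dh > 100
    step <- ifelse(backward, -dh, dh)
    u0 <- idx$fn(state)
    u1 <- idx$fn(.displace(state, dh = step))
    value <- (u1$value - u0$value) / step
    reason <- ifelse(u0$defined & u1$defined, NA_character_,
                     ifelse(!u0$defined, u0$reason, u1$reason))
  } else {
    hi_clip <- state$rh_pct + dh > 100
    lo_clip <- state$rh_pct - dh < 0
    backward <- hi_clip | lo_clip
    up_step <- ifelse(hi_clip, 0, dh)
    dn_step <- ifelse(lo_clip, 0, -dh)
    um <- idx$fn(.displace(state, dh = dn_step))
    up <- idx$fn(.displace(state, dh = up_step))
    value <- (up$value - um$value) / (up_step - dn_step)
    reason <- ifelse(um$defined & up$defined, NA_character_,
                     ifelse(!um$defined, um$reason, up$reason))
  }
  out <- index_value(value, reason)
  out$backward <- backward & out$defined
  out
}

#' Marginal temperature-equivalent change M
#'
#' M = (dU/dT) / (dU/dh), in percentage points of relative humidity per
#' degree C: the humidity change that produces the same index change as a
#' one-degree temperature change.  Small M means the index is relatively
#' humidity-sensitive; large M means temperature dominates.  A
#' humidity-flat index (zero humidity partial) yields the infinite-M
#' sentinel, flagged as `"infinite"` rather than treated as an error.
#'
#' @inheritParams partial_t
#' @return Data frame with columns `m` (numeric, `Inf` for the sentinel),
#'   `status` (`"ok"`, `"infinite"`, `"undefined"`), `reason`.
#' @examples
#' marginal_m("UTCI", air_state(20, 50))
#' marginal_m("WBT", air_state(35, 80))
#' @export
marginal_m <- function(index, state, scheme = fd_scheme()) {
  pt <- partial_t(index, state, scheme)
  ph <- partial_h(index, state, scheme)
  n <- nrow(pt)
  m <- rep(NA_real_, n)
  status <- rep("undefined", n)
  reason <- ifelse(!pt$defined, pt$reason,
                   ifelse(!ph$defined, ph$reason, NA_character_))
  ok <- pt$defined & ph$defined
  inf <- ok & ph$value == 0
  m[inf] <- Inf
  status[inf] <- "infinite"
  reason[inf] <- "M_INFINITE"
  fin <- ok & !inf
  m[fin] <- pt$value[fin] / ph$value[fin]
  status[fin] <- "ok"
  data.frame(m = m, status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' Difference in M between two indices
#'
#' delta-M = M_a - M_b at the same atmospheric state; positive when index
#' `a` needs a larger humidity change to match a degree of warming, i.e.
#' when `b` weights humidity more heavily.  Antisymmetric in its operands.
#' Undefined (with reason) when either M is undefined or infinite.
#'
#' @param index_a,index_b Evaluator functions or registry names.
#' @inheritParams partial_t
#' @return An [index_value()]-style data frame (`value` in % RH per degC).
#' @export
delta_m <- function(index_a, index_b, state, scheme = fd_scheme()) {
  ma <- marginal_m(index_a, state, scheme)
  mb <- marginal_m(index_b, state, scheme)
  ok <- ma$status == "ok" & mb$status == "ok"
  value <- ifelse(ok, ma$m - mb$m, NA_real_)
  reason <- ifelse(ok, NA_character_,
                   ifelse(ma$status != "ok", ma$reason, mb$reason))
  index_value(value, reason)
}

#' Grid of M values over a temperature-humidity lattice
#'
#' Evaluates [marginal_m()] at every lattice point, recording per-cell
#' mask codes: `OK`, `INDEX_UNDEFINED` (the index or a stencil point is
#' undefined there), `M_INFINITE` (humidity-flat), and `OUTSIDE_ENVELOPE`
#' when a [ClimateEnvelope][build_envelope()] marks the condition as not
#' occurring in the present climate.
#'
#' @inheritParams partial_t
#' @param t_axis,h_axis Strictly increasing grid axes (degrees C, % RH).
#' @param envelope Optional climate envelope; cells it excludes are masked.
#' @param wind_ms,tmrt_offset_c,p_kpa Fixed assumptions for the grid: wind
#'   speed, radiant excess over air temperature, pressure.
#' @return An object of class `m_field`: list with `t_axis`, `h_axis`,
#'   `values` (matrix, T by h), `mask` (matrix of codes), `index_name`,
#'   `scheme`.
#' @export
m_grid <- function(index, t_axis = seq(0, 50, by = 0.5),
                   h_axis = seq(1, 100, by = 1),
                   scheme = fd_scheme(), envelope = NULL,
                   wind_ms = 0.5, tmrt_offset_c = 0, p_kpa = 101.325) {
  if (length(t_axis) < 1 || length(h_axis) < 1)
    stop("grid axes must be non-empty", call. = FALSE)
  if (is.unsorted(t_axis, strictly = TRUE) ||
      is.unsorted(h_axis, strictly = TRUE))
    stop("grid axes must be strictly increasing", call. = FALSE)
  idx <- .resolve_index(index)
  grid <- expand.grid(t_c = t_axis, rh_pct = h_axis, KEEP.OUT.ATTRS = FALSE)
  state <- air_state(grid$t_c, grid$rh_pct, wind_ms = wind_ms,
                     tmrt_c = grid$t_c + tmrt_offset_c, p_kpa = p_kpa)
  mm <- marginal_m(idx$fn, state, scheme)
  mask <- ifelse(mm$status == "ok", "OK",
                 ifelse(mm$status == "infinite", "M_INFINITE",
                        "INDEX_UNDEFINED"))
  if (!is.null(envelope)) {
    outside <- !envelope_contains(envelope, state)
    mask[outside] <- "OUTSIDE_ENVELOPE"
  }
  values <- mm$m
  values[mask != "OK"] <- NA_real_
  dim(values) <- c(length(t_axis), length(h_axis))
  dim(mask) <- c(length(t_axis), length(h_axis))
  structure(list(t_axis = t_axis, h_axis = h_axis, values = values,
                 mask = mask, index_name = idx$name, scheme = scheme),
            class = "m_field")
}

#' @export
print.m_field <- function(x, ...) {
  cat("<m_field> ", x$index_name, ": ", length(x$t_axis), " x ",
      length(x$h_axis), " grid; mask: ", sep = "")
  print(table(x$mask))
  invisible(x)
}

#' Serialise an M field to long format
#'
#' @param x An `m_field`.
#' @param row.names,optional,... Passed through (unused).
#' @return Data frame with columns `t_c`, `rh_pct`, `index`,
#'   `m_pct_per_degc`, `mask_code`.
#' @export
as.data.frame.m_field <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  grid <- expand.grid(t_c = x$t_axis, rh_pct = x$h_axis,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(t_c = grid$t_c, rh_pct = grid$rh_pct, index = x$index_name,
             m_pct_per_degc = as.vector(x$values),
             mask_code = as.vector(x$mask), stringsAsFactors = FALSE)
}

#' M at the three canonical regimes for a set of indices
#'
#' Summarises index behaviour at three illustrative atmospheric regimes:
#' low-temperature (20 degC, 50 % RH), hot-humid (35 degC, 80 % RH) and
#' hot-dry (40 degC, 20 % RH).
#'
#' @param indices Named list of evaluators (default: the full registry).
#' @param scheme An [fd_scheme()].
#' @param wind_ms,tmrt_offset_c,p_kpa Fixed assumptions.
#' @return Data frame with columns `regime`, `t_c`, `rh_pct`, `index`, `m`,
#'   `status`.
#' @export
regime_summary <- function(indices = hsi_registry(), scheme = fd_scheme(),
                           wind_ms = 0.5, tmrt_offset_c = 0,
                           p_kpa = 101.325) {
  regimes <- data.frame(
    regime = c("low_temperature", "hot_humid", "hot_dry"),
    t_c = c(20, 35, 40), rh_pct = c(50, 80, 20),
    stringsAsFactors = FALSE)
  state <- air_state(regimes$t_c, regimes$rh_pct, wind_ms = wind_ms,
                     tmrt_c = regimes$t_c + tmrt_offset_c, p_kpa = p_kpa)
  out <- lapply(names(indices), function(nm) {
    mm <- marginal_m(indices[[nm]], state, scheme)
    data.frame(regime = regimes$regime, t_c = regimes$t_c,
               rh_pct = regimes$rh_pct, index = nm, m = mm$m,
               status = mm$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
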
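# Isopleths: lines of constant index value in temperature-humidity space.
# Contours are extracted with the cell-edge linear interpolation of
# grDevices::contourLines (marching squares); cells where the index is
# undefined enter the field as NA and are simply not crossed.

#' Trace an isopleth of a heat stress index
#'
#' @param index Evaluator function or registry name.
#' @param level Index value (degrees C scale) of the contour.
#' @param t_axis,h_axis Strictly increasing grid axes; finer axes give
#'   smaller interpolation error (with the default resolution re-evaluating
#'   the index on the returned points stays within ~0.05 index units of the
#'   level for the smooth indices here).
#' @param wind_ms,tmrt_offset_c,p_kpa Fixed assumptions.
#' @return Object of class `isopleth`: a data frame with columns `branch`,
#'   `order`, `t_c`, `rh_pct` (one or more open polylines, each ordered so
#'   that humidity is non-decreasing), with attributes `index_name` and
#'   `level`.  Zero rows, with a warning, when the level is never bracketed
#'   on the grid.
#' @examples
#' iso <- trace_isopleth("WBT", 20, seq(18, 50, 0.25), seq(1, 100, 0.5))
#' head(iso)
#' @export
trace_isopleth <- function(index, level,
                           t_axis = seq(0, 50, by = 0.25),
                           h_axis = seq(1, 100, by = 0.5),
                           wind_ms = 0.5, tmrt_offset_c = 0,
                           p_kpa = 101.325) {
  if (is.unsorted(t_axis, strictly = TRUE) ||
      is.unsorted(h_axis, strictly = TRUE))
    stop("grid axes must be strictly increasing", call. = FALSE)
  idx <- .resolve_index(index)
  grid <- expand.grid(t_c = t_axis, rh_pct = h_axis, KEEP.OUT.ATTRS = FALSE)
  state <- air_state(grid$t_c, grid$rh_pct, wind_ms = wind_ms,
                     tmrt_c = grid$t_c + tmrt_offset_c, p_kpa = p_kpa)
  u <- idx$fn(state)
  z <- matrix(u$value, nrow = length(t_axis))
  lines <- grDevices::contourLines(t_axis, h_axis, z, levels = level)
  if (length(lines) == 0L) {
    warning("level ", level, " never bracketed on the grid for ",
            idx$name, call. = FALSE)
    out <- data.frame(branch = integer(0), order = integer(0),
                      t_c = numeric(0), rh_pct = numeric(0))
  } else {
    out <- do.call(rbind, lapply(seq_along(lines), function(b) {
      tt <- lines[[b]]$x
      hh <- lines[[b]]$y
      if (length(hh) > 1 && hh[1] > hh[length(hh)]) {  # orient by rising h
        tt <- rev(tt); hh <- rev(hh)
      }
      data.frame(branch = b, order = seq_along(tt), t_c = tt, rh_pct = hh)
    }))
  }
  structure(out, index_name = idx$name, level = level,
            class = c("isopleth", "data.frame"))
}

#' @export
print.isopleth <- function(x, ...) {
  cat("<isopleth> ", attr(x, "index_name"), " = ", attr(x, "level"), ": ",
      length(unique(x$branch)), " branch(es), ", nrow(x), " points\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Evaluate another index along an isopleth
#'
#' The key demonstration that two indices are not on a common scale: along
#' a line of constant value of one index, another index can range widely.
#'
#' @param isopleth An [trace_isopleth()] result.
#' @param index Evaluator function or registry name to evaluate at the
#'   isopleth's points.
#' @param wind_ms,tmrt_offset_c,p_kpa Fixed assumptions.
#' @return Data frame with columns `branch`, `order`, `t_c`, `rh_pct`,
#'   `value`, `defined`, `reason`.  Undefined points are flagged so they
#'   can be excluded from min/max summaries.
#' @examples
#' iso <- trace_isopleth("WBT", 20, seq(18, 50, 0.5), seq(1, 100, 1))
#' along <- evaluate_along(iso, "UTCI")
#' range(along$value[along$defined])
#' @export
evaluate_along <- function(isopleth, index, wind_ms = 0.5,
                           tmrt_offset_c = 0, p_kpa = 101.325) {
  if (nrow(isopleth) == 0L)
    stop("empty isopleth", call. = FALSE)
  idx <- .resolve_index(index)
  state <- air_state(isopleth$t_c, isopleth$rh_pct, wind_ms = wind_ms,
                     tmrt_c = isopleth$t_c + tmrt_offset_c, p_kpa = p_kpa)
  u <- idx$fn(state)
  data.frame(branch = isopleth$branch, order = isopleth$order,
             t_c = isopleth$t_c, rh_pct = isopleth$rh_pct,
             value = u$value, defined = u$defined, reason = u$reason,
             stringsAsFactors = FALSE)
}
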
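# Climate envelope: for each relative-humidity bin, the maximum co-occurring
# air temperature in a climate record.  Conditions above that maximum are
# "conditions that have not occurred" and get hatched/masked in M fields.
# A synthetic envelope shaped by a wet-bulb cap stands in when no
# reanalysis-derived file is supplied.

.new_envelope <- function(bins, provenance) {
  stopifnot(all(c("bin_lower", "bin_upper", "t_max_c") %in% names(bins)))
  structure(bins, provenance = provenance,
            class = c("climate_envelope", "data.frame"))
}

#' Build a climate envelope from observations
#'
#' Bins relative humidity into intervals `(lower, upper]` of width
#' `bin_width` covering (0, 100] and records the maximum co-occurring
#' temperature per bin.  Bins containing no observation carry `NA` as an
#' explicit no-data marker.
#'
#' @param observations Data frame with columns `t_c` and `rh_pct` (an
#'   [air_state()] works).
#' @param bin_width Bin width in percentage points; must divide 100.
#' @param provenance Text recorded on the envelope.
#' @return Object of class `climate_envelope`: data frame with columns
#'   `bin_lower`, `bin_upper`, `t_max_c`.
#' @examples
#' obs <- data.frame(t_c = c(30, 35, 20), rh_pct = c(45, 50, 90))
#' build_envelope(obs, bin_width = 10)
#' @export
build_envelope <- function(observations, bin_width = 1,
                           provenance = "observations") {
  if (NROW(observations) == 0L)
    stop("no observations supplied", call. = FALSE)
  stopifnot(all(c("t_c", "rh_pct") %in% names(observations)))
  if (bin_width <= 0 || abs(100 / bin_width - round(100 / bin_width)) > 1e-9)
    stop("bin_width must divide 100", call. = FALSE)
  edges <- seq(0, 100, by = bin_width)
  # (lower, upper]: bin 1 is (0, w]; an exact 0 lands in bin 1 as well.
  idx <- pmax(1L, ceiling(observations$rh_pct / bin_width - 1e-12))
  idx <- pmin(idx, length(edges) - 1L)
  t_max <- rep(NA_real_, length(edges) - 1L)
  agg <- tapply(observations$t_c, idx, max)
  t_max[as.integer(names(agg))] <- as.numeric(agg)
  .new_envelope(data.frame(bin_lower = edges[-length(edges)],
                           bin_upper = edges[-1], t_max_c = t_max),
                provenance)
}

#' @export
print.climate_envelope <- function(x, ...) {
  cat("<climate_envelope> ", attr(x, "provenance"), ": ", nrow(x),
      " bins, ", sum(is.na(x$t_max_c)), " without data\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Does a state fall inside the climate envelope?
#'
#' A state is inside when its temperature does not exceed the maximum
#' co-occurring temperature of its humidity bin (closed upper bound).
#' No-data bins are conservatively treated as outside.
#'
#' @param envelope A `climate_envelope`.
#' @param state An [air_state()] or data frame with `t_c`, `rh_pct`.
#' @return Logical vector.
#' @export
envelope_contains <- function(envelope, state) {
  bw <- envelope$bin_upper[1] - envelope$bin_lower[1]
  idx <- pmax(1L, ceiling(state$rh_pct / bw - 1e-12))
  idx <- pmin(idx, nrow(envelope))
  tm <- envelope$t_max_c[idx]
  !is.na(tm) & state$t_c <= tm
}

#' Synthetic climate envelope
#'
#' A stand-in for a reanalysis-derived envelope, shaped by the two robust
#' features of the observed present-day distribution: wet-bulb temperature
#' rarely exceeds about 31 degrees C, and dry-bulb extremes top out near
#' 55 degrees C.  Per bin, the maximum temperature is the smaller of the
#' hard cap and the temperature at which the wet-bulb reaches `wbt_cap_c`
#' at that humidity (root-found on the Davies-Jones evaluator), which makes
#' it monotone non-increasing in humidity.
#'
#' @param t_cap_c Hard dry-bulb cap, degrees C.
#' @param wbt_cap_c Wet-bulb cap, degrees C.
#' @param bin_width Humidity bin width, percentage points.
#' @param p_kpa Pressure for the wet-bulb root-finding.
#' @return A `climate_envelope` with provenance `"synthetic-v1"`.
#' @export
synthetic_envelope <- function(t_cap_c = 55, wbt_cap_c = 31, bin_width = 1,
                               p_kpa = 101.325) {
  if (t_cap_c <= 0 || wbt_cap_c <= 0)
    stop("caps must be positive", call. = FALSE)
  edges <- seq(0, 100, by = bin_width)
  upper <- edges[-1]
  wbt_at <- function(t, h) hsi_wbt(air_state(t, h, p_kpa = p_kpa))$value
  t_max <- vapply(upper, function(h) {
    if (wbt_at(t_cap_c, h) <= wbt_cap_c) return(t_cap_c)
    stats::uniroot(function(t) wbt_at(t, h) - wbt_cap_c,
                   lower = wbt_cap_c - 1, upper = t_cap_c,
                   tol = 1e-3)$root
  }, numeric(1))
  .new_envelope(data.frame(bin_lower = edges[-length(edges)],
                           bin_upper = upper, t_max_c = t_max),
                "synthetic-v1")
}

#' Read or write a climate envelope as CSV
#'
#' The CSV schema is `rh_bin_upper_pct, t_max_c`, one row per bin in
#' increasing humidity order; no-data bins have an empty `t_max_c` field.
#' This is the interchange format for externally derived envelopes (e.g.
#' from reanalysis records).
#'
#' @param path File path.
#' @return `read_envelope` returns a `climate_envelope` whose provenance is
#'   the file name; `write_envelope` invisibly returns `path`.
#' @export
read_envelope <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rh_bin_upper_pct", "t_max_c") %in% names(df)))
    stop("envelope CSV must have columns rh_bin_upper_pct, t_max_c",
         call. = FALSE)
  if (any(!is.finite(df$rh_bin_upper_pct)))
    stop("malformed envelope row(s): ",
         paste(which(!is.finite(df$rh_bin_upper_pct)), collapse = ", "),
         call. = FALSE)
  df <- df[order(df$rh_bin_upper_pct), , drop = FALSE]
  bw <- df$rh_bin_upper_pct[1]
  .new_envelope(data.frame(bin_lower = df$rh_bin_upper_pct - bw,
                           bin_upper = df$rh_bin_upper_pct,
                           t_max_c = as.numeric(df$t_max_c)),
                basename(path))
}

#' @rdname read_envelope
#' @param envelope A `climate_envelope`.
#' @export
write_envelope <- function(envelope, path) {
  df <- data.frame(rh_bin_upper_pct = envelope$bin_upper,
                   t_max_c = envelope$t_max_c)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
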
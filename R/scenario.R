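# Scenario audit: how coupled temperature/specific-humidity perturbations
# (the signature of soil-moisture or irrigation changes: wetter surface ->
# cooler, moister air) rank against each index's response.  Opposite-signed
# rank correlations between the humidity change and two indices' changes
# mean the two indices would support opposite conclusions about whether
# added moisture worsens heat stress.

#' Scenario records
#'
#' @param t0_c Baseline air temperature, degrees C.
#' @param h0_pct Baseline relative humidity, percent.
#' @param dt_c Temperature perturbation, degrees C.
#' @param dq_kgkg Specific-humidity perturbation, kg/kg.
#' @return Data frame of class `scenario_records`.
#' @export
scenario_records <- function(t0_c, h0_pct, dt_c, dq_kgkg) {
  n <- max(length(t0_c), length(h0_pct), length(dt_c), length(dq_kgkg))
  out <- data.frame(t0_c = rep_len(as.numeric(t0_c), n),
                    h0_pct = rep_len(as.numeric(h0_pct), n),
                    dt_c = rep_len(as.numeric(dt_c), n),
                    dq_kgkg = rep_len(as.numeric(dq_kgkg), n))
  class(out) <- c("scenario_records", "data.frame")
  out
}

#' Apply scenario perturbations
#'
#' Perturbed temperature is `t0 + dt`; the specific-humidity perturbation
#' `dq` is added to the baseline specific humidity and converted back to
#' relative humidity at the perturbed temperature.  Records whose perturbed
#' state is unphysical (supersaturated or negative humidity) are flagged,
#' not dropped silently.
#'
#' @param records A [scenario_records()] data frame.
#' @param p_kpa Pressure used for the humidity conversions.
#' @param wind_ms Wind speed attached to both states.
#' @return List with elements `baseline` and `perturbed` ([air_state()]s of
#'   the unflagged records) and `flagged` (logical vector over all input
#'   records).
#' @export
perturb <- function(records, p_kpa = 101.325, wind_ms = 0.5) {
  q0 <- specific_humidity(records$t0_c, records$h0_pct, p_kpa)
  q1 <- q0 + records$dq_kgkg
  t1 <- records$t0_c + records$dt_c
  e1 <- q1 * p_kpa / (0.622 + 0.378 * q1)
  rh1 <- 100 * e1 / .esat_buck(t1)
  flagged <- !is.finite(rh1) | q1 < 0 | rh1 > 100 + 1e-9
  rh1 <- pmin(rh1, 100)
  list(baseline = air_state(records$t0_c[!flagged],
                            records$h0_pct[!flagged],
                            wind_ms = wind_ms, p_kpa = p_kpa),
       perturbed = air_state(t1[!flagged], rh1[!flagged],
                             wind_ms = wind_ms, p_kpa = p_kpa),
       flagged = flagged)
}

#' Per-record, per-index changes under scenario perturbations
#'
#' @param records A [scenario_records()] data frame.
#' @param indices Named list of index evaluators.
#' @param p_kpa,wind_ms Fixed assumptions.
#' @return Data frame with one row per (usable record, index): columns
#'   `record`, `index`, `dq_kgkg`, `delta` (index change, degrees C scale),
#'   `defined` (FALSE when the index is undefined at either endpoint).
#'   The attribute `flagged` carries the unphysical-record mask.
#' @export
index_changes <- function(records, indices = hsi_registry(),
                          p_kpa = 101.325, wind_ms = 0.5) {
  if (NROW(records) == 0L) stop("no records supplied", call. = FALSE)
  pr <- perturb(records, p_kpa = p_kpa, wind_ms = wind_ms)
  used <- which(!pr$flagged)
  out <- lapply(names(indices), function(nm) {
    u0 <- indices[[nm]](pr$baseline)
    u1 <- indices[[nm]](pr$perturbed)
    data.frame(record = used, index = nm,
               dq_kgkg = records$dq_kgkg[used],
               delta = u1$value - u0$value,
               defined = u0$defined & u1$defined,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), flagged = pr$flagged)
}

#' Rank correlations between two sequences
#'
#' Kendall's tau (the tie-corrected tau-b, as computed by [stats::cor()])
#' and Spearman's rho.  Requires at least 3 pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `kendall_tau`, `spearman_rho`, `n`.
#' @export
rank_correlations <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    return(list(kendall_tau = NA_real_, spearman_rho = NA_real_,
                n = length(x)))
  list(kendall_tau = stats::cor(x, y, method = "kendall"),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       n = length(x))
}

#' Rank-correlation audit of index changes against humidity changes
#'
#' For each index, rank-correlates the per-record index change with the
#' specific-humidity change dq.  A positive correlation means conditions
#' that gained moisture (and, in coupled scenarios, lost temperature) raise
#' that index; the `reversal` flag is set when two indices carry
#' opposite-signed Kendall tau, i.e. when the choice of index would reverse
#' the conclusion.
#'
#' @inheritParams index_changes
#' @return Object of class `hsi_audit`: list with `changes` (the
#'   [index_changes()] table), `summary` (per-index `kendall_tau`,
#'   `spearman_rho`, `sign`, `n_used`, `n_flagged`), and `reversal`
#'   (logical).
#' @examples
#' rec <- synthesize_soil_moisture_scenarios(50, seed = 1)
#' audit(rec, hsi_registry()[c("WBT", "UTCI")])
#' @export
audit <- function(records, indices = hsi_registry(), p_kpa = 101.325,
                  wind_ms = 0.5) {
  ch <- index_changes(records, indices, p_kpa = p_kpa, wind_ms = wind_ms)
  n_flagged_phys <- sum(attr(ch, "flagged"))
  summ <- do.call(rbind, lapply(names(indices), function(nm) {
    sub <- ch[ch$index == nm & ch$defined, ]
    rc <- rank_correlations(sub$dq_kgkg, sub$delta)
    data.frame(index = nm, kendall_tau = rc$kendall_tau,
               spearman_rho = rc$spearman_rho,
               sign = ifelse(is.na(rc$kendall_tau), NA_integer_,
                             as.integer(sign(rc$kendall_tau))),
               n_used = rc$n,
               n_flagged = n_flagged_phys +
                 sum(ch$index == nm & !ch$defined),
               stringsAsFactors = FALSE)
  }))
  taus <- summ$kendall_tau[!is.na(summ$kendall_tau)]
  reversal <- length(taus) >= 2 && min(taus) < 0 && max(taus) > 0
  structure(list(changes = ch, summary = summ, reversal = reversal),
            class = "hsi_audit")
}

#' @export
print.hsi_audit <- function(x, ...) {
  cat("<hsi_audit> reversal:", x$reversal, "\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Synthetic soil-moisture perturbation scenarios
#'
#' Emulates the structure of soil-moisture counterfactual experiments over
#' heatwave conditions: hot, fairly dry baselines with anti-correlated
#' temperature and specific-humidity perturbations (moister soil cools and
#' moistens the air, drier soil does the opposite).  Baselines are drawn
#' uniformly over 30-42 degrees C and 15-60 % RH; dq uniformly over +/- 2
#' g/kg; dt = coupling * dq(g/kg) + Gaussian noise.
#'
#' @param n Number of records, at least 10.
#' @param seed Integer seed; the draw is fully reproducible and the
#'   caller's RNG state is untouched.
#' @param coupling_c_per_gkg Temperature response per g/kg of added
#'   moisture, degrees C; must be negative (evaporative cooling).
#' @param noise_sd_c Std. dev. of the temperature noise, degrees C.
#' @return A [scenario_records()] data frame.
#' @export
synthesize_soil_moisture_scenarios <- function(n, seed,
                                               coupling_c_per_gkg = -0.7,
                                               noise_sd_c = 0.2) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (coupling_c_per_gkg >= 0)
    stop("coupling must be negative (moistening cools)", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  t0 <- stats::runif(n, 30, 42)
  h0 <- stats::runif(n, 15, 60)
  dq_gkg <- stats::runif(n, -2, 2)
  dt <- coupling_c_per_gkg * dq_gkg + stats::rnorm(n, 0, noise_sd_c)
  scenario_records(t0, h0, dt, dq_gkg / 1000)
}

#' Read or write scenario records as CSV
#'
#' Schema: `t0_c, h0_pct, dt_c, dq_kgkg`.
#'
#' @param path File path.
#' @return `read_scenarios` returns a [scenario_records()] data frame.
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t0_c", "h0_pct", "dt_c", "dq_kgkg")
  if (!all(need %in% names(df)))
    stop("scenario CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("malformed scenario row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  scenario_records(df$t0_c, df$h0_pct, df$dt_c, df$dq_kgkg)
}

#' @rdname read_scenarios
#' @param records A [scenario_records()] data frame.
#' @export
write_scenarios <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
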
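# Independent oracles used across the suite.  These deliberately take
# different routes from the package implementation: the wet-bulb oracle
# solves the isobaric psychrometric energy balance instead of inverting
# equivalent potential temperature, and the rank-correlation oracles are
# brute-force O(n^2) / rank-transform constructions.

# Buck saturation curve, duplicated here so the oracle does not call the
# package.
oracle_esat <- function(t_c) 0.61121 * exp(17.502 * t_c / (240.97 + t_c))

# Psychrometric wet-bulb: esat(Tw) - e = cp p / (0.622 L) (T - Tw).
oracle_wbt_psychrometric <- function(t_c, rh_pct, p_kpa = 101.325) {
  mapply(function(t, rh) {
    e <- rh / 100 * oracle_esat(t)
    gam <- 1005 * p_kpa / (0.622 * 2.501e6)
    stats::uniroot(function(tw) oracle_esat(tw) - e - gam * (t - tw),
                   c(-60, t + 1e-9), tol = 1e-10)$root
  }, t_c, rh_pct)
}

# Kendall tau-b by exhaustive pair enumeration with tie correction.
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
    else if (dx == 0) tie_x <- tie_x + 1
    else if (dy == 0) tie_y <- tie_y + 1
    else if (sign(dx) == sign(dy)) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Spearman rho as Pearson correlation of mid-ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Per-bin maximum by explicit looping over bins.
oracle_envelope_tmax <- function(t_c, rh_pct, bin_width) {
  edges <- seq(0, 100, by = bin_width)
  vapply(seq_len(length(edges) - 1), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    sel <- if (i == 1) rh_pct >= lo & rh_pct <= hi
           else rh_pct > lo & rh_pct <= hi
    if (!any(sel)) NA_real_ else max(t_c[sel])
  }, numeric(1))
}

# Wrap a plain U(T, h) function as an index evaluator, for synthetic
# fields with known derivatives.
synthetic_index <- function(f) {
  function(state) index_value(f(state$t_c, state$rh_pct))
}
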
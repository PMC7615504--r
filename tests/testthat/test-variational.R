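# Finite-difference partials, M, delta-M and the M-field machinery,
# checked on synthetic fields with known derivatives and on the real
# indices via property-style invariants.

test_that("partials are exact on linear synthetic fields", {
  s <- air_state(c(10, 25, 40), c(20, 50, 80))
  u_t <- synthetic_index(function(t, h) t)
  u_lin <- synthetic_index(function(t, h) 2 * t + h)
  for (mode in c("forward", "central")) {
    sch <- fd_scheme(mode = mode)
    expect_equal(partial_t(u_t, s, sch)$value, c(1, 1, 1))
    expect_equal(partial_h(u_t, s, sch)$value, c(0, 0, 0))
    expect_equal(partial_t(u_lin, s, sch)$value, c(2, 2, 2))
    expect_equal(partial_h(u_lin, s, sch)$value, c(1, 1, 1))
  }
})

test_that("humidity partial takes a flagged backward step at the h = 100 boundary", {
  s <- air_state(30, 100)
  u <- synthetic_index(function(t, h) t + 0.5 * h)
  ph <- partial_h(u, s)
  expect_true(ph$backward)
  expect_equal(ph$value, 0.5)
  ph_int <- partial_h(u, air_state(30, 50))
  expect_false(ph_int$backward)
  ph_c <- partial_h(u, s, fd_scheme(mode = "central"))
  expect_true(ph_c$backward)
  expect_equal(ph_c$value, 0.5)
})

test_that("M is the ratio of partials, with the infinite sentinel for humidity-flat fields", {
  s <- air_state(25, 50)
  m1 <- marginal_m(synthetic_index(function(t, h) t + 0.1 * h), s)
  expect_equal(m1$m, 10)
  expect_equal(m1$status, "ok")
  m2 <- marginal_m(synthetic_index(function(t, h) t), s)
  expect_identical(m2$m, Inf)
  expect_equal(m2$status, "infinite")
  expect_equal(m2$reason, "M_INFINITE")
  # undefined index propagates with its reason
  m3 <- marginal_m("UTCI", air_state(55, 20))
  expect_equal(m3$status, "undefined")
  expect_equal(m3$reason, "T_LIMIT")
})

test_that("M is invariant under monotone rescaling of the index", {
  states <- air_state(c(25, 35, 20, 40), c(40, 70, 60, 20))
  for (nm in c("UTCI", "WBT", "SWBGT")) {
    base <- hsi_index(nm)
    m0 <- marginal_m(base, states)$m
    transforms <- list(
      function(v) 2 * v,
      function(v) v^3 + v,
      function(v) exp(v / 20))
    for (f in transforms) {
      wrapped <- function(state) {
        u <- base(state)
        index_value(f(u$value), u$reason)
      }
      m1 <- marginal_m(wrapped, states)$m
      expect_equal(m1, m0, tolerance = 0.02)
    }
  }
})

test_that("forward and central differences converge under step halving", {
  s <- air_state(25, 40)
  gap <- function(d) {
    abs(marginal_m("UTCI", s, fd_scheme(d, d, "forward"))$m -
        marginal_m("UTCI", s, fd_scheme(d, d, "central"))$m)
  }
  g1 <- gap(0.2); g2 <- gap(0.1); g3 <- gap(0.05)
  expect_lt(g2, 0.75 * g1)  # first-order decay
  expect_lt(g3, 0.75 * g2)
  # for the iterative wet-bulb the two schemes agree closely at the
  # default step, which sits above the solver noise floor
  mfwd <- partial_t("WBT", air_state(30, 50), fd_scheme(mode = "forward"))
  mcen <- partial_t("WBT", air_state(30, 50), fd_scheme(mode = "central"))
  expect_lt(abs(mfwd$value - mcen$value), 0.01)
})

test_that("delta-M is antisymmetric, zero on itself, undefined on infinite M", {
  s <- air_state(c(25, 35), c(40, 70))
  ab <- delta_m("UTCI", "WBT", s)$value
  ba <- delta_m("WBT", "UTCI", s)$value
  expect_equal(ab, -ba)
  expect_equal(delta_m("WBT", "WBT", s)$value, c(0, 0))
  flat <- synthetic_index(function(t, h) t)
  out <- delta_m(flat, "WBT", s)
  expect_false(any(out$defined))
  expect_equal(out$reason, c("M_INFINITE", "M_INFINITE"))
})

test_that("m_grid masks cells by cause and is constant for linear fields", {
  t_ax <- seq(20, 40, by = 5)
  h_ax <- seq(20, 80, by = 15)
  fld <- m_grid(synthetic_index(function(t, h) t + 0.2 * h), t_ax, h_ax)
  expect_true(all(fld$mask == "OK"))
  expect_true(all(abs(fld$values - 5) < 1e-9))
  # humidity-flat field: all infinite
  fld_inf <- m_grid(synthetic_index(function(t, h) t), t_ax, h_ax)
  expect_true(all(fld_inf$mask == "M_INFINITE"))
  expect_true(all(is.na(fld_inf$values)))
  # UTCI grid into hot-humid territory picks up INDEX_UNDEFINED cells
  fld_u <- m_grid("UTCI", seq(30, 48, 2), seq(40, 100, 10))
  expect_true(any(fld_u$mask == "INDEX_UNDEFINED"))
  expect_true(all(is.finite(fld_u$values[fld_u$mask == "OK"])))
  expect_error(m_grid("UTCI", numeric(0), h_ax), "non-empty")
})

test_that("envelope masking in m_grid matches envelope_contains exactly", {
  t_ax <- seq(20, 50, by = 5)
  h_ax <- seq(10, 90, by = 20)
  env <- build_envelope(data.frame(t_c = c(45, 35, 25),
                                   rh_pct = c(15, 50, 85)),
                        bin_width = 25)
  fld <- m_grid("SWBGT", t_ax, h_ax, envelope = env)
  grid <- expand.grid(t_c = t_ax, rh_pct = h_ax)
  outside <- !envelope_contains(env, grid)
  expect_equal(as.vector(fld$mask) == "OUTSIDE_ENVELOPE", outside)
})

test_that("the WBT M field varies far less than the UTCI field", {
  t_ax <- seq(5, 45, by = 2.5)
  h_ax <- seq(10, 90, by = 5)
  f_wbt <- m_grid("WBT", t_ax, h_ax)
  f_utci <- m_grid("UTCI", t_ax, h_ax)
  idr <- function(f) {
    v <- f$values[f$mask == "OK"]
    diff(stats::quantile(v, c(0.1, 0.9)))
  }
  expect_lt(idr(f_wbt), idr(f_utci))
})

test_that("regime summary reproduces the three-regime agreement pattern", {
  reg <- regime_summary()
  m_of <- function(regime, index) reg$m[reg$regime == regime &
                                          reg$index == index]
  # hot-humid: the seven indices in rough agreement all have low M
  for (nm in c("AT", "HI", "UTCI", "WBT", "HUMIDEX", "WBGT_INDOOR",
               "SWBGT"))
    expect_lte(m_of("hot_humid", nm), 10)
  # low-temperature: UTCI is temperature-dominated, WBT is not
  expect_gt(m_of("low_temperature", "UTCI"), m_of("low_temperature", "WBT"))
  expect_gt(m_of("low_temperature", "UTCI"), 15)
  # hot-dry: HI and UTCI stand out against WBT
  expect_gt(m_of("hot_dry", "HI"), m_of("hot_dry", "WBT"))
  expect_gt(m_of("hot_dry", "UTCI"), m_of("hot_dry", "WBT"))
  expect_true(all(reg$status == "ok"))
})

test_that("regime ordering is consistent whether humidity is RH or specific humidity", {
  # re-express each index in (T, q) coordinates through the psychro
  # conversions and recompute the analogue of M with dq steps
  m_q <- function(name, t, h) {
    base <- hsi_index(name)
    q0 <- specific_humidity(t, h)
    dq <- 1e-4
    dt <- 0.1
    u <- function(tt, qq)
      base(air_state(tt, rh_from_specific_humidity(qq, tt)))$value
    (u(t + dt, q0) - u(t, q0)) / dt / ((u(t, q0 + dq) - u(t, q0)) / dq)
  }
  pts <- list(c(20, 50), c(35, 80), c(40, 20))
  for (p in pts) {
    mh <- vapply(c("WBT", "UTCI", "HI"), function(nm)
      marginal_m(nm, air_state(p[1], p[2]))$m, numeric(1))
    mq <- vapply(c("WBT", "UTCI", "HI"), function(nm)
      m_q(nm, p[1], p[2]), numeric(1))
    expect_equal(order(mh), order(mq))
  }
})
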
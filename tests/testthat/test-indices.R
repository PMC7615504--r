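# Index evaluators against independent oracles and their defined/undefined
# contracts.

test_that("wet-bulb equals dry-bulb at saturation and tracks the psychrometric oracle", {
  expect_equal(hsi_wbt(air_state(c(10, 20, 30, 38), 100))$value,
               c(10, 20, 30, 38), tolerance = 0.02)
  # frozen values of the isobaric psychrometric-balance oracle; the
  # Davies-Jones thermodynamic wet-bulb sits within a few tenths of it
  expect_equal(hsi_wbt(air_state(30, 50))$value, 22.0109, tolerance = 0.3)
  expect_equal(hsi_wbt(air_state(40, 20))$value, 22.0536, tolerance = 0.3)
  # the thermodynamic (pseudoadiabatic) and psychrometric wet-bulbs are
  # distinct quantities that drift apart towards hot-dry air; agreement to
  # a few tenths over the meteorological range is the expected behaviour
  grid <- expand.grid(t = seq(0, 45, by = 5), h = seq(10, 100, by = 15))
  dj <- hsi_wbt(air_state(grid$t, grid$h))$value
  or <- oracle_wbt_psychrometric(grid$t, grid$h)
  expect_true(all(abs(dj - or) < 0.7))
  expect_true(all(dj <= grid$t + 1e-9))
})

test_that("wet-bulb is invariant along an isobaric adiabatic-saturation path", {
  # cooling dT while evaporating dq = -cp dT / L leaves the wet-bulb fixed
  cp <- 1005; L <- 2.501e6
  for (base in list(c(35, 40), c(30, 60), c(40, 25), c(25, 80))) {
    q1 <- specific_humidity(base[1], base[2])
    w1 <- hsi_wbt(air_state(base[1], base[2]))$value
    for (dT in c(-1, -2)) {
      t2 <- base[1] + dT
      h2 <- rh_from_specific_humidity(q1 - cp * dT / L, t2)
      w2 <- hsi_wbt(air_state(t2, h2))$value
      expect_lt(abs(w2 - w1), 0.05)
    }
  }
})

test_that("NOAA heat index reproduces the published chart and branches", {
  # 86 degF / 50 % -> 88 degF on NOAA's chart
  expect_equal(hsi_heat_index(air_state(30, 50))$value, 31.1,
               tolerance = 0.1)
  # below the 80 degF threshold the simple-average branch stays near T
  expect_lt(abs(hsi_heat_index(air_state(20, 50))$value - 20), 1)
  # monotone in humidity on the regression branch
  hh <- seq(30, 90, by = 5)
  hi <- hsi_heat_index(air_state(rep(35, length(hh)), hh))$value
  expect_true(all(diff(hi) > 0))
  # the low-RH adjustment keeps the surface continuous enough to stay
  # above air temperature in hot conditions
  expect_true(all(hsi_heat_index(air_state(seq(32, 44, 2), 5))$defined))
})

test_that("humidex fixed point, frozen value, and undefined at zero humidity", {
  # dewpoint 15 degC -> e ~ 17.16 hPa -> excess 3.98 degC
  rh <- 100 * vapour_pressure(15, 100) / saturation_vapour_pressure(30)
  expect_equal(hsi_humidex(air_state(30, rh))$value, 33.97,
               tolerance = 0.02)
  # e = 10 hPa is the formula's fixed point: humidex = T
  rh10 <- 100 * 1.0 / saturation_vapour_pressure(30)
  expect_equal(hsi_humidex(air_state(30, rh10))$value, 30, tolerance = 0.1)
  hh <- seq(10, 100, by = 10)
  expect_true(all(diff(hsi_humidex(air_state(rep(30, 10), hh))$value) > 0))
  out <- hsi_humidex(air_state(30, 0))
  expect_false(out$defined)
  expect_equal(out$reason, "RH_ZERO")
})

test_that("apparent temperature follows the shaded Steadman form", {
  # e = 0, wind w: AT = T - 0.7 w - 4
  expect_equal(hsi_apparent_temperature(air_state(30, 0, wind_ms = 2))$value,
               30 - 1.4 - 4)
  # frozen hand evaluation at e = 4.50073 kPa
  expect_equal(hsi_apparent_temperature(air_state(35, 80))$value, 45.5024,
               tolerance = 1e-3)
  hh <- seq(0, 100, by = 10)
  expect_true(all(diff(hsi_apparent_temperature(
    air_state(rep(30, 11), hh))$value) > 0))
  ww <- c(0.5, 1, 2, 4)
  expect_true(all(diff(hsi_apparent_temperature(
    air_state(rep(30, 4), 50, wind_ms = ww))$value) < 0))
})

test_that("sWBGT is the Australian-dialect linear form", {
  expect_equal(hsi_swbgt(air_state(35, 0))$value, 0.567 * 35 + 3.94)
  expect_equal(hsi_swbgt(air_state(35, 80))$value,
               0.567 * 35 + 0.393 * 45.0073 + 3.94, tolerance = 1e-3)
  grid <- expand.grid(t = seq(20, 45, 5), h = seq(10, 90, 20))
  v <- hsi_swbgt(air_state(grid$t, grid$h))$value
  expect_true(all(v[grid$h == 90] > v[grid$h == 10]))
})

test_that("WBGT-indoor is a convex combination of wet-bulb and dry-bulb", {
  expect_equal(hsi_wbgt_indoor(air_state(c(25, 35), 100))$value, c(25, 35),
               tolerance = 0.02)
  grid <- expand.grid(t = seq(20, 45, 5), h = seq(10, 90, 20))
  s <- air_state(grid$t, grid$h)
  w <- hsi_wbt(s)$value
  g <- hsi_wbgt_indoor(s)$value
  expect_true(all(g >= w - 0.02 & g <= grid$t + 0.02))
})

test_that("Ts adds the dryness offset 4.5 (1 - f^2) to the wet-bulb", {
  s <- air_state(rep(32, 3), c(0, 50, 100))
  w <- hsi_wbt(s)$value
  ts <- hsi_ts_mora(s)$value
  expect_equal(ts - w, c(4.5, 3.375, 0))
})

test_that("UTCI enforces its validity box with specific reasons", {
  expect_equal(hsi_utci(air_state(55, 20))$reason, "T_LIMIT")
  expect_equal(hsi_utci(air_state(-55, 50))$reason, "T_LIMIT")
  expect_equal(hsi_utci(air_state(40, 70))$reason, "VP_LIMIT")  # e = 5.17 kPa
  expect_equal(hsi_utci(air_state(25, 50, wind_ms = 0.3))$reason,
               "WIND_LIMIT")
  expect_equal(hsi_utci(air_state(25, 50, wind_ms = 18))$reason,
               "WIND_LIMIT")
  expect_equal(hsi_utci(air_state(25, 50, tmrt_c = 100))$reason,
               "TMRT_LIMIT")
  expect_true(hsi_utci(air_state(25, 50, tmrt_c = 90))$defined)
})

test_that("UTCI polynomial reproduces a hand evaluation of the coefficient table", {
  # (20 degC, 50 %, 0.5 m/s, Tmrt = Ta): offset summed by hand from the
  # published table gives ~1.263, i.e. UTCI ~ 21.26
  expect_equal(hsi_utci(air_state(20, 50))$value, 21.263, tolerance = 0.01)
  # smooth and bounded over its validity box: no runaway coefficient
  grid <- expand.grid(t = seq(-10, 48, 2), h = seq(5, 100, 5))
  s <- air_state(grid$t, grid$h)
  u <- hsi_utci(s)
  v <- u$value[u$defined]
  expect_true(all(v > grid$t[u$defined] - 15 & v < grid$t[u$defined] + 20))
})

test_that("the high WBT and UTCI scales coincide: WBT 35 lies near UTCI 55", {
  grid <- expand.grid(t = seq(44, 50, 0.1), h = seq(30, 60, 0.5))
  s <- air_state(grid$t, grid$h)
  w <- hsi_wbt(s)$value
  sel <- abs(w - 35) <= 0.05
  expect_gt(sum(sel), 0)
  u <- hsi_utci(s[sel, , drop = FALSE])
  expect_gt(sum(u$defined), 0)
  expect_true(all(u$value[u$defined] >= 50 & u$value[u$defined] <= 60))
})

test_that("evaluators are deterministic and the registry is complete", {
  reg <- hsi_registry()
  expect_setequal(names(reg), c("WBT", "HI", "HUMIDEX", "AT", "UTCI",
                                "WBGT_INDOOR", "SWBGT", "TS_MORA"))
  grid <- expand.grid(t = seq(-5, 55, 10), h = seq(0, 100, 25))
  s <- air_state(grid$t, grid$h)
  for (nm in names(reg)) {
    out1 <- reg[[nm]](s)
    out2 <- reg[[nm]](s)
    expect_identical(out1, out2)
    expect_true(all(is.finite(out1$value[out1$defined])))
    expect_true(all(!is.na(out1$reason[!out1$defined])))
  }
  expect_identical(hsi_index("utci"), hsi_utci)
  expect_error(hsi_index("NOPE"), "unknown index")
})
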
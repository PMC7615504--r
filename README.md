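# heatmarg

Heat stress indices (HSIs) — wet-bulb temperature (WBT), the NOAA heat
index (HI), humidex, Steadman's apparent temperature (AT), the UTCI,
indoor and simplified WBGT, and the Mora-derived Ts — all combine air
temperature and humidity into a single °C-valued number, but on
incompatible scales and with very different weightings of humidity.  For
interventions that trade temperature against humidity (irrigation, urban
greening, soil-moisture anomalies), the estimated effect on "heat stress"
can change *sign* with the choice of index.

`heatmarg` is for climate-health and biometeorology researchers who need
to know **where in temperature–humidity space their indices disagree,
and by how much**.  It evaluates the eight indices above under fixed
wind/radiation assumptions (wind 0.5 m s⁻¹, mean radiant temperature
equal to air temperature) and compares them through the **marginal
temperature-equivalent change**

$$M(T,h) = \frac{\partial U/\partial T}{\partial U/\partial h}
\quad\left[\% \text{ RH per } ^\circ\text{C}\right],$$

the relative-humidity change that moves index $U$ as much as a 1 °C
temperature change — the gradient of the index's isopleth in the
$(T,h)$ plane.  Because the index's own units cancel, $M$ is comparable
across indices calibrated to completely different scales.  The package
also traces isopleths, masks conditions outside a present-climate
envelope, and audits coupled $(\Delta T, \Delta q)$ perturbation
scenarios by rank-correlating per-index changes against the moisture
change.

## Worked example

```r
library(heatmarg)

# Index values are not mutually comparable...
s <- air_state(t_c = c(20, 35, 40), rh_pct = c(50, 80, 20))
cbind(s[1:2], wbt = hsi_wbt(s)$value, utci = hsi_utci(s)$value)
#>   t_c rh_pct      wbt     utci
#> 1  20     50 13.73251 21.26277
#> 2  35     80 31.81327 48.28417
#> 3  40     20 21.76431 44.54416

# ...but M puts their sensitivities on one scale.  At 20 °C / 50 % RH,
# a 1 °C warming moves UTCI as much as a 25-point RH change (UTCI is
# temperature-dominated there), against only ~6 points for WBT:
marginal_m("UTCI", air_state(20, 50))$m   # 25.20407
marginal_m("WBT",  air_state(20, 50))$m   # 6.321301

# Along the single WBT = 20 °C isopleth, UTCI ranges from ~24 to ~46 °C:
iso   <- trace_isopleth("WBT", 20, seq(18, 50, 0.25), seq(1, 100, 0.5))
along <- evaluate_along(iso, "UTCI")
range(along$value[along$defined])
#> [1] 23.96658 45.89863

# Soil-moisture-style scenarios (cooler+moister vs warmer+drier):
# moisture-driven indices rise with added humidity, temperature-driven
# ones fall — index choice reverses the conclusion.
rec <- synthesize_soil_moisture_scenarios(200, seed = 1)
audit(rec, hsi_registry()[c("WBT", "TS_MORA", "UTCI", "HI")])
#> <hsi_audit> reversal: TRUE
#>    index kendall_tau spearman_rho sign n_used n_flagged
#>      WBT      0.8933       0.9853    1    200         0
#>  TS_MORA      0.7826       0.9389    1    200         0
#>     UTCI     -0.6739      -0.8542   -1    200         0
#>       HI      0.0342       0.0506    1    200         0
```

The rank correlations are between each index's change and the
specific-humidity change Δq across 200 synthetic records; `reversal:
TRUE` records that at least two indices carry opposite-signed Kendall
tau.  UTCI's polynomial validity limits (vapour pressure ≤ 5 kPa, air
temperature ≤ 50 °C, among others) are always enforced: out-of-range
states come back flagged (`VP_LIMIT`, `T_LIMIT`, ...), never silently
extrapolated.

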
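Package: heatmarg
Title: Marginal Temperature-Equivalent Comparison of Heat Stress Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the heat stress indices commonly used in
    climate-health research (Davies-Jones wet-bulb temperature, NOAA heat
    index, humidex, Steadman shaded apparent temperature, the UTCI
    polynomial with its published validity limits, indoor and simplified
    wet-bulb globe temperature, and the Mora-derived Ts metric) and
    compares their sensitivity to air temperature versus humidity on a
    common scale via the marginal temperature-equivalent change M, the
    ratio of the finite-difference partial derivatives of an index with
    respect to temperature and relative humidity.  Includes isopleth
    tracing in temperature-humidity space, M fields with climate-envelope
    masking, and a rank-correlation audit showing how the choice of index
    can reverse conclusions about coupled temperature-moisture
    perturbations such as those induced by soil moisture or irrigation
    changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
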
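---
title: "Comparing heat stress indices with the marginal temperature-equivalent change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing heat stress indices with the marginal temperature-equivalent change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmarg)
```

## The problem

Heat stress indices (HSIs) condense temperature, humidity and sometimes
wind and radiation into a single number meant to track physiological heat
strain.  The indices in common use in climate-health work — wet-bulb
temperature (WBT), the NOAA heat index (HI), humidex, Steadman's apparent
temperature (AT), the UTCI, indoor and simplified WBGT, and the
Mora-derived Ts — are all quoted in °C, but they are calibrated to
different scales and weight humidity very differently.  Two consequences
matter for applied work:

1. values of different indices cannot be compared directly (a WBT of
   20 °C corresponds to UTCI values anywhere from the mid-20s to above
   40 °C depending on the temperature–humidity combination), and
2. for interventions that trade temperature against humidity — irrigation,
   urban greening, soil-moisture anomalies — the *sign* of the estimated
   heat-stress response can depend on the index chosen.

This package quantifies those disagreements on a common scale.

## The marginal temperature-equivalent change

For an index $U(T, h)$ evaluated at temperature $T$ (°C) and relative
humidity $h$ (%, 0–100 scale), define

$$M(T, h) \;=\; \frac{\partial U/\partial T}{\partial U/\partial h},$$

the humidity change (in percentage points of RH) that moves the index as
much as a 1 °C temperature change.  $M$ is the (negative reciprocal)
gradient of the index's isopleth in the $(T, h)$ plane, and because the
index's own units cancel in the ratio, $M$ can be compared freely across
indices and across atmospheric states.  Small $M$ means the index is
relatively humidity-sensitive; large $M$ means temperature dominates.  $M$
is invariant under any strictly increasing rescaling of the index (the
test suite checks this to within the finite-difference error), which is
exactly why it works as a scale-free comparator.

Partial derivatives are estimated by finite differences
(`partial_t()`, `partial_h()`), forward by default with a central scheme
retained as a numerical cross-check.  Not all the indices are
analytically differentiable (WBT is defined implicitly through an
iterative solve), so numerical differentiation is the honest common
denominator.

### Numerical choices

* **Steps** `delta_t = delta_h = 0.1` (°C, percentage points).  The
  wet-bulb solver is converged to better than 0.01 °C; differencing at a
  step of 0.01 would divide solver quantisation noise by a small number,
  while 0.1 keeps the truncation error of the forward scheme negligible
  for these smooth surfaces.  The suite verifies that the forward/central
  gap shrinks to first order as the step is halved.
* **Boundary** at $h = 100\,\%$: a forward humidity step would enter
  supersaturation, so a backward step is taken and flagged
  (`backward = TRUE`) instead.
* **Humidity-flat indices** return an infinite-$M$ sentinel
  (`status = "infinite"`), not an error: a field renderer must be able to
  draw a grid containing such cells.
* **Undefined index values** (e.g. UTCI outside its validity box)
  propagate as masked cells with the reason code, never as extrapolated
  numbers.
* **Radiant temperature under differencing**: the mean radiant
  temperature is displaced together with air temperature, preserving the
  radiant excess, consistent with the package-wide assumption
  $T_{mrt} = T_a$ (+ optional fixed offset).

## The index battery and its fixed assumptions

All evaluators are pure, vectorised mappings from an `air_state` (T, RH,
wind, Tmrt, pressure) to an `index_value` with an explicit
defined/undefined contract.  Fixed assumptions, chosen once for the whole
package: wind 0.5 m s⁻¹ (the lowest wind for which the UTCI reference
conditions were fitted), $T_{mrt} = T_a$ (reasonable for shaded/indoor
settings; radiation effects are out of scope), pressure 101.325 kPa
(exposed as a parameter because WBT and specific humidity depend on it).

* **WBT** — thermodynamic wet-bulb after Davies-Jones (2008): the
  temperature at which a saturated parcel at the same pressure matches the
  parcel's equivalent potential temperature (Bolton 1980, eq. 39).  The
  inversion is a vectorised bisection on the saturated $\theta_e$ curve,
  which is strictly increasing in the wet-bulb; 60 halvings from the
  bracket $[-85\,°C, T]$ put the result far below the 0.01 °C tolerance
  deterministically, with no dependence on a Newton starting guess.  Note
  this thermodynamic quantity differs from the psychrometer (ventilated
  wet-thermometer) wet-bulb by a few tenths of a degree in hot dry air;
  the test suite uses the psychrometric energy balance as an independent
  oracle with that distinction in mind.
* **HI** — the NOAA Rothfusz regression in °F with both official
  adjustment terms, and NOAA's simple average-with-temperature formula
  below the 80 °F threshold.  The below-threshold branch is *close to*
  but not exactly the air temperature; the package follows NOAA's
  published procedure rather than the common paraphrase "HI equals T
  below 26.7 °C".
* **Humidex** — Meteorological Service of Canada form,
  $T + 0.5555\,(e_{hPa} - 10)$, with $e$ derived from the dewpoint;
  undefined at zero humidity because the dewpoint is.
* **AT** — Steadman's shaded apparent temperature including wind,
  $T + 0.33\,e_{hPa} - 0.70\,v - 4.00$.
* **UTCI** — the published 6th-order polynomial approximation (Bröde et
  al. 2012) in $T_a$, $v$, $T_{mrt}-T_a$ and vapour pressure, with the
  published validity limits enforced: $T_a \in [-50, 50]$ °C,
  $e \le 5$ kPa, $v \in [0.5, 17]$ m s⁻¹, $T_{mrt}-T_a \in [-30, 70]$ K.
  Out-of-range states return flagged undefined values with a specific
  reason code — applying these limits is frequently forgotten in applied
  work, so the package makes silent extrapolation impossible.
* **WBGT-indoor** — Bernard's combination
  $0.67\,T_{wb} + 0.33\,T_a - 0.048\log_{10}(v)\,(T_a - T_{wb})$ (the
  radiation-free WBGT used when no black-globe measurement exists), with
  the Davies-Jones wet-bulb and the package wind assumption.
* **sWBGT** — $0.567\,T_a + 0.393\,e_{hPa} + 3.94$.
* **Ts** — $T_{wb} + 4.5\,(1 - f^2)$ with $f$ the *fractional* relative
  humidity.  The dryness bonus $4.5(1-f^2)$ is only physically sensible
  with $f$ on 0–1, although the rest of the package works on the 0–100
  scale; the fractional convention is fixed here and documented.

Where a formula family circulates in several unit dialects (AT, sWBGT),
the hPa-based dialect was adopted once; every golden value in the test
suite is generated from these same constants, never transcribed from
plotted figures.

Saturation vapour pressure uses Buck (1981) over liquid water, isolated
behind `saturation_vapour_pressure()` so an alternative fit could be
swapped in one place.  Since no single reference formula is canonical
across the index literature, the package treats its own psychrometric
layer as the source of truth for all derived quantities.

## Isopleths and M fields

`trace_isopleth()` extracts lines of constant index value by
marching-squares cell-edge interpolation (via `grDevices::contourLines`);
every traced contour is re-evaluated through its index as a self-check,
and stays within 0.05 index units of the level at the default grid
resolution (0.25 °C × 0.5 %).  `evaluate_along()` evaluates a *different*
index along such a line — the directest demonstration that two indices do
not share a scale.

`m_grid()` evaluates $M$ over a lattice (default $T \in [0, 50]$ °C step
0.5, $h \in [1, 100]$ % step 1) and records per-cell mask codes that
renderers can hatch differently: `INDEX_UNDEFINED`, `M_INFINITE`,
`OUTSIDE_ENVELOPE`.

Three illustrative regimes summarise the comparison
(`regime_summary()`): low-temperature (20 °C, 50 %), hot-humid (35 °C,
80 %) and hot-dry (40 °C, 20 %).  The reproducible pattern: AT, HI and
UTCI are temperature-dominated in the low-temperature regime where WBT's
$M$ stays low; HI and UTCI develop a high-$M$ zone in hot-dry conditions;
and all of AT, HI, UTCI, WBT, humidex, WBGT-indoor and sWBGT converge to
low $M$ (≤ 10 % RH per °C) in the hot-humid regime, where humidity
genuinely limits sweat evaporation.

```{r regimes}
subset(regime_summary(), index %in% c("WBT", "UTCI", "HI"))
```

## The climate envelope

Comparisons are only meaningful over conditions that actually occur.  A
`climate_envelope` stores, per 1 % humidity bin, the maximum co-occurring
temperature in a climate record; `envelope_contains()` masks everything
above it.  `build_envelope()` accepts any (T, h) observation sequence, so
an envelope derived from reanalysis (e.g. hourly 2 m temperature and
dewpoint converted to RH) can be loaded through the same CSV interface
(`read_envelope()`).

Because shipping a reanalysis extract is neither possible nor necessary
here, `synthetic_envelope()` generates a stand-in shaped by the two
robust features of the present-day distribution: wet-bulb temperatures
rarely exceed about 31 °C, and dry-bulb extremes top out near 55 °C.  Per
bin the cap temperature is root-found on the WBT evaluator, making the
envelope monotone non-increasing in humidity.  It is labelled
`synthetic-v1` in its provenance field and is a *shape* stand-in, not a
climatology: it has no spatial structure, no seasonality, and a hard
rather than probabilistic boundary.

## The scenario audit

Soil-moisture and irrigation perturbations move temperature and humidity
*jointly*: a wetter surface cools and moistens the near-surface air.  The
audit machinery applies records of (baseline T, baseline RH, ΔT, Δq) —
with the humidity perturbation specified in specific humidity, converted
through the psychrometric layer at fixed pressure — computes the change
in every index, and rank-correlates each index's change against Δq
(Kendall's tau-b, which tolerates the ties produced by rounded model
output, and Spearman's rho).  Opposite-signed correlations between two
indices mean the choice of index reverses the conclusion; `audit()`
raises a `reversal` flag in exactly that case.

`synthesize_soil_moisture_scenarios()` generates records with the
structure of such experiments: heatwave baselines drawn uniformly over
30–42 °C and 15–60 % RH, moisture perturbations uniform within ±2 g/kg,
and ΔT = −0.7 °C per g/kg of added moisture plus Gaussian noise
(sd 0.2 °C).  The coupling constant sits deliberately *below* the
isobaric evaporative limit of ≈2.5 °C per g/kg (cp/L): boundary-layer
adjustment, entrainment and advection mean realised surface couplings in
land-atmosphere experiments are substantially weaker than the adiabatic
bound.  Any coupling strictly between 0 and the adiabatic limit produces
the same qualitative physics; under it, added moisture raises the
equivalent potential temperature, so WBT and Ts rise with Δq while the
temperature-dominated indices (UTCI, AT) fall — the sign-reversal
phenomenon the audit is designed to expose, which the acceptance suite
verifies across ten seeds.

What the synthetic generator does **not** emulate: spatially correlated
baselines, the dependence of the coupling on the baseline soil-moisture
regime, non-Gaussian perturbation tails, and any change in wind or
radiation.  Passing the audit on synthetic data therefore demonstrates
the *mechanism* (index choice can reverse the conclusion under
anti-correlated ΔT/Δq forcing), not the magnitude of any particular
published experiment; the CSV interface (`read_scenarios()`) exists so
real modelled deltas can be audited identically.

## Problem sizes and runtime

The shipped tests and the acceptance script run on desk-scale problems
chosen as the coarsest resolutions at which each property is cleanly
resolved: isopleths on 0.25 °C × 0.5 % grids, M-field comparisons on a
2.5 °C × 5 % lattice, audits of 100–200 records over 10 seeds.  The whole
suite completes in well under a minute on one core; all results are
deterministic given the documented seeds.

## Known limitations

* The UTCI here is the polynomial approximation, not the underlying
  multi-node physiological model; inside the validity box the fit error
  of the published polynomial is inherited as-is.
* WBT is the thermodynamic (pseudoadiabatic) wet-bulb; users comparing
  against psychrometer readings should expect differences of a few tenths
  of a degree, growing towards hot-dry extremes.
* The HI surface keeps NOAA's piecewise structure; its derivative is
  discontinuous at the 80 °F branch boundary, which shows up as a step
  in M (rendered honestly, not smoothed).
* Fixed wind and $T_{mrt} = T_a$ restrict the comparison to the
  temperature–humidity plane.  The `air_state` container carries wind and
  radiant temperature, so the same finite-difference machinery could be
  pointed at those axes, but no such operations are shipped.
* $M$ compares *marginal* sensitivities.  It says nothing about which
  index better predicts health outcomes — it locates the atmospheric
  conditions where the choice between indices matters.
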
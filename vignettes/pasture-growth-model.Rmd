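---
title: "A daily weather-driven model of pasture growing conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A daily weather-driven model of pasture growing conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasturegrow)
```

## The model and its assumptions

`pasturegrow` estimates how favourable each day is for cool-season pasture
growth from nothing but latitude, daily minimum/maximum temperature and
rainfall. The daily environmental relative growth rate is the product of
four factors, each a dimensionless 0–1 multiplier expressing how far one
environmental variable is from non-limiting:

$$\mathrm{rgr\_env}(t) = \mathrm{rgr\_asw}(t)\,\cdot\,
  \mathrm{rgr\_temp}(t)\,\cdot\,\mathrm{rgr\_dl}(t)\,\cdot\,
  \mathrm{rgr\_sbio}(t)$$

summed over the season into `cum_rgr_env`. The model is deliberately
*relative*: it does not predict forage mass in kg/ha. Absolute yield
depends on species, fertility, pH and management; the claim is only that,
at a given site and management, observed cumulative growth is
approximately linear in `cum_rgr_env`, and the `validate` functions fit
and test exactly that relation.

Multiplying the factors assumes limitations act independently and
proportionally (a day at half water and half temperature potential is a
quarter day), the standard first-order choice when interactions cannot be
estimated from available data.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `asw_max` | mm | site-specific (9 in = 228.6 mm; 5 in = 127 mm are typical silt-loam values) | maximum plant-available soil water |
| cardinal temperatures | °C | 0 / 10 / 20 / 30 (C3) | trapezoidal temperature response |
| daylength thresholds | h | 8 / 12 / 13 | spring ramp and late-summer plateau edge |
| `tsum_start` | °C·day | 280 (some sites fit better at 300) | thermal time triggering spring growth |
| `et_pan_fraction` | — | 0.80 (C3), 0.75 (C4) | plant ET as a fraction of pan evaporation |
| pan strategy | — | Hargreaves–Samani-style surrogate | pan evaporation from Ra, T, ΔT |

The warm-season (`c4_defaults()`) preset shifts the lower cardinal points
to 10 and 30 °C and the ET fraction to 0.75. Its *upper* cardinal points
and daylength thresholds have no established values in this framework;
they default to placeholders (35 / 45 °C, C3 daylength thresholds) and are
flagged as such in the documentation — review them before serious C4 use.

## Design choices where the design was open

**Pan evaporation.** The intended formulation is a regional regression of
open-pan evaporation on potential solar radiation, mean temperature and
the diurnal temperature range (a cloud-cover proxy). Regression
coefficients are inherently local, so the package's default is a
Hargreaves–Samani-style surrogate using exactly those three predictors,
$pan = 0.0023\,(R_a/2.45)\,(T + 17.8)\,\sqrt{\Delta T}$, and a generic
linear strategy (`et_params("linear", coefficients = ...)`) accepts any
locally fitted coefficients. Both floor at zero.

**Solar geometry.** Declination and the Earth–Sun distance factor use the
Spencer (1971) Fourier series rather than the common single-harmonic
approximation: at latitude 39.6° the single harmonic deviates from a
NOAA-style ephemeris by up to 0.17 h of daylength, while the Spencer
series stays within 0.05 h, which the test suite verifies against an
independently coded Meeus-style oracle. Daylength is geometric (no
refraction), consistent with the round 8/12/13 h thresholds. The day
angle always uses a 365-day year; the leap-year error is far below model
precision.

**Thermal time.** Tsum accumulates `max(0, t_mean)` from 1 January —
negative means are ignored, never subtracted — with base temperature 0 °C,
consistent with the C3 minimum growth temperature. Once `tsum_start` is
reached, growth stays active for the rest of the calendar year; autumn
shutdown comes from the temperature and daylength factors, not a second
gate.

**Daylength phase.** Ascending vs descending is decided by comparing the
day of year to the solstice (doy 172, 173 in leap years), not by
differencing consecutive daylengths — deterministic and independent of
step order. Ascending days longer than 12 h return 1 (plateau clamp).

**Water balance.** ASW starts at capacity on the first simulated day
(humid temperate winters recharge the soil; `asw_init_frac` overrides
this), carries across year boundaries while Tsum and `cum_rgr_env` reset,
and ET is withdrawn every day of the year including before growth
initiation, since the water balance is a soil property, not a canopy one.
The update adds precipitation, subtracts ET, then clamps to
`[0, asw_max]`; both clamps can never bind on the same day, so the order
of flooring and capping is immaterial. Excess water is implicitly
runoff/drainage.

**Validation statistics.** SDreg uses residual degrees of freedom,
$\sqrt{SSE/(n-k)}$ with $k$ estimated coefficients. AAPE is the standard
mean absolute percent error with the observed value in the denominator;
observations of exactly 0 make it undefined and are a caller-visible
error, not a silent exclusion. Dummy variables use reference-level coding
with the earliest year / first treatment as reference, and the intercept
is tested against zero with a two-sided t test at p = 0.05.

## What the synthetic generator emulates — and what it does not

`generate_weather()` produces a humid temperate mid-latitude climate:
daily mean temperature as a sinusoid (minimum near 15 January, default
annual mean 11 °C, amplitude 11.5 °C) plus Gaussian noise (sd 3 °C), a
symmetric diurnal range (mean 11 °C), and rainfall as an independent
Bernoulli wet-day draw (default p = 0.33 per month) with exponential
amounts (mean 9 mm), totalling roughly 1100 mm/yr — values a
northeastern-US agronomist would call typical of Allegheny Plateau
pasture. An optional two-state Markov persistence parameter lengthens wet
and dry spells; it is off by default because independent draws suffice to
exercise the water bucket. Drought is imposed by scaling *amounts* inside
a day-of-year window after occurrence is drawn, so a baseline and a
drought run with the same seed share wet days — a variance-reduction
device that makes monotonicity tests sharp.

The generator does **not** emulate autocorrelated synoptic temperature
swings, rainfall seasonality beyond the monthly wet-day vector, convective
spatial mismatch between a station and a pasture, snow, or frost-pocket
topography. Passing tests on synthetic data therefore demonstrate the
internal correctness and sensitivity structure of the model — not that
any particular real site is predicted within a stated error.

`generate_observations()` plants a known linear relation
(default intercept −3, slope 0.56 on the percent-of-maximum scale, noise
sd 5) with optional year/treatment offsets, floors at zero, and maps back
to kg/ha through a recorded affine scale, so the full
generate → simulate → fit loop can be checked for parameter recovery.

## Numerical and degenerate-input conventions

Temperature gaps of at most 3 consecutive days are linearly interpolated
on ingestion; longer gaps are a hard error. Missing precipitation is set
to 0 with a warning — interpolation never invents rainfall. Missing whole
calendar days inside the file's span are inserted and handled by the same
policy. Inverted temperatures (t_max < t_min), negative rainfall,
duplicate days and out-of-range day-of-year values are errors that name
the offending line. Latitudes beyond ±66.5° (polar day/night) are
rejected. Responses at exact breakpoints take the plateau value
(`rgr_temp(10) = 1`, `rgr_asw` at exactly half capacity = 1, ascending
daylength at exactly 12 h = 1). Simulation is fully deterministic:
re-running with identical inputs is bit-identical.

## Problem sizes used by the test suite

The suite favours small deterministic fixtures: single synthetic years
(365 days) for engine behaviour, 10,000 random daily steps for
water-balance conservation, 20 paired years for drought monotonicity,
five seeded years for annual-magnitude checks, and 100 seeded replicates
of the three-year end-to-end recovery experiment — sizes chosen so the
whole suite runs in well under a minute while keeping the binomial
counting bounds of the coverage checks meaningful.

## Known limitations

Single-layer bucket hydrology (no runoff/drainage partitioning, no snow);
no nitrogen or defoliation feedback, so management effects appear as
regression offsets rather than mechanism; a surrogate pan-evaporation
formula unless local coefficients are supplied; C4 upper cardinal points
are placeholders; and the model's output is a relative index that must be
scaled through the validation regression to speak in kg/ha.
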
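---
title: "Comparing eight Antarctic krill growth models under common forcing"
author: "krillgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing eight Antarctic krill growth models under common forcing}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Growth of Antarctic krill (*Euphausia superba*) integrates the two
environmental drivers that matter most for the species' habitat quality:
water temperature, which sets metabolic rates, and food availability, for
which chlorophyll a (or particulate organic carbon derived from it) is the
standard large-scale proxy. Over two decades a series of growth models has
been published, each calibrated to a particular region, season and type of
food data. Applied to the *same* forcing they disagree — sometimes even on
the sign of growth. This package implements eight of those models behind a
single contract so that their response surfaces, seasonal trajectories and
spatial patterns can be compared under identical, controlled conditions.

## The model suite

Three empirical models:

* **atkinson2006** — an instantaneous daily-growth-rate (DGR) regression:
  additive terms quadratic in body length `L`, quadratic in temperature
  `T`, and saturating (Michaelis–Menten) in chlorophyll `F`:
  `DGR = a0 + aL*L + aL2*L^2 + aF*F/(kF+F) + aT*T + aT2*T^2` (mm d⁻¹).
  Stage-specific fits; the "all krill" set takes over at 35 mm.
* **wiedenmann2008** — a moult-based composite: krill hold a constant
  length through each intermoult period (IMP) and jump by a moult
  increment. IMPs come from the temperature-only exponential decay
  `IMP(T) = i0 * exp(-decay*T)` (about 30 d at 0 °C); increments come from
  the Atkinson-type percent-increment regression evaluated at the mean
  conditions experienced over the IMP.
* **tarling2006** — the same composite engine but with the
  length/stage/temperature IMP family, expressed as the reciprocal of a
  moulting rate (hence hyperbolic in its drivers). The juvenile IMP peaks
  near 3 °C and is insensitive to length; the adult-female IMP is shortest
  at 0.5 °C (about 10 d at 0 °C and 35 mm) and lengthens with body size.

Five mechanistic models:

* **hofmann2000 / fach2002** — clearance-rate feeding on POC (50 mg C per
  mg chlorophyll) minus a Q10 temperature-dependent metabolic cost, mapped
  through the length–mass coupling; the daily length change is capped at
  +0.25 mm d⁻¹ (the cap the original authors imposed), with shrinkage
  allowed. The Fach variant differs mainly by a much weaker temperature
  dependence (Q10 1.3 vs 2.5).
* **jager2015** — a simplified DEB (DEBkiss) budget on the volumetric
  length `Lv = shape * L`: assimilation ∝ `f·Lv²`, somatic maintenance ∝
  `Lv³`, a fixed allocation fraction κ, Arrhenius temperature correction.
  Growth stops where `κ·assimilation = maintenance`, i.e. near 60 mm
  physical length at `f = 1`. The original model assumed unlimited food;
  as in the intercomparison protocol we scale food by the Holling type II
  response of the photoperiod-DEB parameterization (an `unlimited_food`
  config flag restores the original assumption).
* **bahlburg2021** — the photoperiod-DEB variant: the same budget with a
  bounded, monotone day-length scaling `s(P) = 0.5 + 0.5·P/24` applied to
  both ingestion and maintenance, so short days reduce respiration (and
  hence starvation losses) relative to the simplified variant.
* **ryabov2017** — energy partitioning: Holling II intake with a low
  half-saturation (0.5 mg m⁻³, reflecting its in-situ calibration data)
  pays metabolism first, the residual drives somatic growth; a winter
  metabolic switch multiplies the metabolic term.

All eight expose the same surface: `init` (state from an initial length),
daily stepping through the engine, an instantaneous `rate` under constant
conditions (for moult models: increment/IMP, with IMP-mean conditions
equal to the point values in that limit), required forcing fields and
citation-tagged calibration metadata.

## Parameter registry and its quality control

The registry (`inst/extdata/registry/`) holds one citation-tagged file per
source model. The coefficient sets were assembled from the cited original
publications' model structures and then gated, as this package's own
quality-control step, on the quantitative anchors the intercomparison
literature reports for exactly these implementations:

* IMP of ~30 d (temperature-only) vs ~10 d (adult female, 35 mm) at 0 °C,
  a ratio near 3;
* peak juvenile daily growth rate above 0.3 mm d⁻¹ at 26 mm in mid-January;
* the +0.25 mm d⁻¹ cap of the clearance-feeding models, binding from
  chlorophyll 1.4–1.7 mg m⁻³ upward at some temperatures;
* the ~60 mm DEB asymptote under unlimited food;
* opposite growth signs at (1 mg m⁻³, 0 °C, 26 mm): simplified-DEB
  negative, Tarling composite positive;
* the cold-end optimum (near −1 °C) of the Tarling composite versus the
  warm-side optimum (>1 °C) of the Kawaguchi-IMP composite;
* higher chlorophyll requirements of every mechanistic model than of any
  empirical model for 0.1 mm d⁻¹ at 1 °C;
* the seasonal cross-model ordering (empirical models and the
  energy-partitioning model above the other four mechanistic models) and
  the 19–60 mm range of final lengths on a South-Orkney-like season.

These anchors are enforced by the test suite; a registry edit that breaks
any of them fails the build. Registry loading itself refuses coefficient
sets without citations and stage labels outside
{juvenile, adult female, adult male, all krill}.

## The common simulation protocol

* **Window**: 1 November to 15 April, both endpoints inclusive — 166 daily
  states. The recorded length for a date is the length at the start of
  that day, so all models share the 26 mm initial record and day-one
  ensemble spread is zero.
* **Initial length**: 26 mm, the smallest size all eight models are
  calibrated for; the engine refuses smaller starts.
* **Ice rule**: an ice-covered day overrides all model physics — growth is
  zero and metabolism is not charged; moult clocks are extended by one day
  per ice day. A `charge_ice_metabolism` flag (default off) instead charges
  maintenance at zero food, for sensitivity runs.
* **Stage switching**: at 35 mm. Moult-based models re-evaluate stage only
  at moult events (length cannot change mid-IMP); the daily-rate models
  re-evaluate daily.
* **First IMP**: drawn from the IMP function at day-one conditions with
  zero elapsed days — the moult phase at the start of a run is not
  observable, so this deterministic choice is made once and exposed via
  the init contract.
* **Moult increments**: negative increments are applied as shrinkage (no
  floor); `increment_floor = 0` is available for sensitivity runs.
* **Integrators**: the rate/ODE models step with forward Euler by default
  or classical RK4 with the forcing interpolated linearly between daily
  values (midpoint evaluation at the day-pair mean). The moult-based
  models are event processes, not ODEs; they always step daily, and an
  RK4 request falls back to the event stepping. On seasonal forcing the
  Euler/RK4 final lengths agree within 0.1 mm for every model, which the
  suite asserts.
* **Determinism**: identical config, registry and forcing give
  bit-identical results; grid cells are independent, so chunking or
  execution order cannot change a field.

## Forcing

`synthetic_soi_forcing()` emulates a productive season south of the South
Orkney Islands: SST follows a sinusoid pinned exactly to −1.5 °C on
1 November and to a configurable mid-February peak (default 1.2 °C);
chlorophyll is a Gaussian bloom (default peak 20 January, width 28 d,
amplitude 0.9 mg m⁻³) on a 0.3 mg m⁻³ baseline, so the series starts at
~0.3 mg m⁻³ and declines from late February onward. Photoperiod comes from
the sunrise equation (solar declination, horizon at −0.833°, no twilight)
at the configured latitude (−60.7°). Optional Gaussian noise is seeded and
reproducible. These defaults are the package's fixed study conditions, not
tuning knobs.

What the generator deliberately does not emulate: day-to-day synoptic
variability and cloud-gap artefacts of satellite products, ice-edge bloom
timing, heterotrophic and ice-algal food (set to zero throughout, as in
the common protocol), and regional water-mass structure. Tests passing on
this forcing therefore show protocol correctness and the documented
between-model contrasts — not skill against field observations.

Gridded climatologies are ingested from long-format plain-text tables
(`lon, lat, date, value[, units]`): block-mean downsampling to the target
resolution (default 0.25°), day-of-year averaging over the available years
on a 365-day calendar (29 February folds into day 59), optional 15-day
circular rolling mean, and flagging (not dropping) of cell-days with fewer
than a configurable number of samples. Unit metadata mismatches fail
loudly. The polar-front mask removes cells north of a longitude-complete
boundary polyline; a helper averages weekly boundary lines per longitude.

## Analytics and their numerical choices

* **Response surfaces** default to SST ∈ [−2, 4] °C and chlorophyll ∈
  [0, 5] mg m⁻³ in 0.05 steps — ranges representative of circumpolar
  habitats; the exact axes are a documented choice. Photoperiod enters as
  an explicit argument (default 20 h, a mid-January high-latitude value)
  because only the photoperiod-DEB model is sensitive to it and the
  surface definition should not hide that dependency behind a latitude.
* **required_chl** inverts the (verified monotone) chlorophyll response by
  bisection on [0, 20] mg m⁻³ to 10⁻³ mg m⁻³, returning a flagged
  "unreachable" when a cap or plateau sits below the target.
* **Ensemble spread and divergence maps** use the population standard
  deviation (divide by the number of models): the eight models are the
  entire ensemble, not a sample. The coefficient of variation uses
  SD/|mean| and is flagged undefined where |mean| < 0.1 mm rather than
  silently dropped.
* The IMP validity question at temperatures below 1 °C or above 3 °C —
  where the two IMP families diverge most — is handled by *not* clamping:
  the functions are evaluated as published and the divergence is the
  result, though the adult-female moulting rate errors out if it would
  turn non-positive far outside its range.

## Problem sizes

The shipped tests run the full eight-model ensemble on the 166-day
synthetic season, dense rate grids of a few tens of thousands of points
for the cap and monotonicity assertions, and 3-cell toy grids for the
grid-protocol invariants; the whole suite completes in well under a
minute. Circumpolar grids (>10⁵ cells) are supported by the same code
path — cells are independent — but require externally supplied gridded
climatologies, which are not bundled.

## Known limitations

* Reproduction/spawning fluxes of the DEB models, larval stages and
  overwintering physiology beyond each model's published metabolic switch
  are out of scope.
* Registry coefficients are gated on published summary anchors rather
  than on the original calibration datasets; absolute trajectories should
  be read as faithful to the intercomparison's reported behaviour, not as
  re-validations of the original models.
* The chlorophyll:POC ratio is a fixed 50; in the field it varies
  seasonally by a factor of a few, which biases the POC-driven models.
* NetCDF ingestion is not provided; gridded data enter via the plain-text
  long format described above.

## A worked comparison

```{r example}
library(krillgrowth)

forcing <- synthetic_soi_forcing()
ens <- simulate_ensemble("all", forcing, simulation_config())
print(ens)
spread <- ensemble_spread(ens)
plot(ens)

surf <- response_surface("tarling2006")
print(surf)

required_chl("ryabov2017", target_rate = 0.1, sst = 1)
```
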
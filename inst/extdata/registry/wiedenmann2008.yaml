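id: wiedenmann2008
label: "Wiedenmann et al. (2008) moult-based composite"
type: empirical
citation: >
  Wiedenmann J, Cresswell K, Mangel M (2008) Temperature-dependent growth
  of Antarctic krill: predictions for a changing climate from a cohort
  model. Marine Ecology Progress Series 358:191-202.
calibration:
  region: "composite: Indian-sector IMPs with Scotia Sea increments"
  season: "austral summer"
  temperature_range_c: [-1.0, 4.0]
  chl_range: "satellite-derived chlorophyll a"
  food_proxy: "chlorophyll a (satellite)"
functions:
  # Composite model: moult increments from the Atkinson et al. (2006)
  # increment functions, intermoult periods from Kawaguchi et al. (2006).
  # food_scaling multiplies chlorophyll before the increment function; the
  # original study downscaled food availability, disabled here by default.
  composite:
    "all krill":
      citation: "Wiedenmann et al. (2008), composite configuration"
      units: "dimensionless"
      coefficients:
        food_scaling: 1.0
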
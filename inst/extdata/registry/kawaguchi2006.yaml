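id: kawaguchi2006
label: "Kawaguchi et al. (2006) temperature-only intermoult period"
type: empirical
citation: >
  Kawaguchi S, Candy SG, King R, Naganobu M, Nicol S (2006) Modelling
  growth of Antarctic krill. I. Growth trends with sex, length, season,
  and region. Marine Ecology Progress Series 306:1-15.
calibration:
  region: "Indian sector of the Southern Ocean"
  season: "austral summer fishing seasons"
  temperature_range_c: [-1.0, 4.0]
  chl_range: "not food-dependent (temperature-only IMP)"
  food_proxy: "none"
functions:
  # Intermoult period (days): imp = i0 * exp(-decay * T)
  imp:
    "all krill":
      citation: "Kawaguchi et al. (2006), exponential IMP-temperature fit"
      units: "days; T degC"
      coefficients:
        i0: 30.0
        decay: 0.35
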
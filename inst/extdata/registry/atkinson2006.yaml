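id: atkinson2006
label: "Atkinson et al. (2006) instantaneous growth rate"
type: empirical
citation: >
  Atkinson A, Shreeve RS, Hirst AG, Rothery P, Tarling GA, Pond DW,
  Korb RE, Murphy EJ, Watkins JL (2006) Natural growth rates in Antarctic
  krill (Euphausia superba): II. Predictive models based on food,
  temperature, body length, sex, and maturity stage. Limnology and
  Oceanography 51:973-987.
calibration:
  region: "Scotia Sea, South Georgia, northern Antarctic Peninsula"
  season: "austral summer (including spring-like southern stations)"
  temperature_range_c: [-1.0, 5.0]
  chl_range: "satellite-derived chlorophyll a, roughly 0-5 mg m-3"
  food_proxy: "chlorophyll a (satellite)"
functions:
  # Daily growth rate (mm d-1):
  #   dgr = a0 + aL*L + aL2*L^2 + aF*chl/(kF + chl) + aT*T + aT2*T^2
  dgr:
    "all krill":
      citation: "Atkinson et al. (2006), all-krill daily growth rate fit"
      units: "mm d-1; L mm, T degC, chl mg m-3"
      coefficients:
        a0: -0.066
        aL: 0.002
        aL2: -0.000061
        aF: 0.385
        kF: 0.328
        aT: 0.0078
        aT2: -0.0101
    juvenile:
      citation: "Atkinson et al. (2006), juvenile daily growth rate fit"
      units: "mm d-1; L mm, T degC, chl mg m-3"
      coefficients:
        a0: -0.066
        aL: 0.002
        aL2: -0.000061
        aF: 0.42
        kF: 0.328
        aT: 0.0078
        aT2: -0.0101
  # Growth increment at moult, percent of body length per intermoult period:
  #   gi_percent = g0 + gF*chl/(kF + chl) + gT*T + gT2*T^2
  # increment (mm) = gi_percent * L / 100
  increment:
    juvenile:
      citation: "Atkinson et al. (2006), juvenile moult-increment fit"
      units: "percent of body length per moult"
      coefficients:
        g0: -1.15
        gF: 14.6
        kF: 0.33
        gT: 0.46
        gT2: -0.46
    "all krill":
      citation: "Atkinson et al. (2006), all-krill moult-increment fit"
      units: "percent of body length per moult"
      coefficients:
        g0: -1.0
        gF: 9.0
        kF: 0.33
        gT: 0.3
        gT2: -0.3
    "adult female":
      citation: "Atkinson et al. (2006), adult-female moult-increment fit"
      units: "percent of body length per moult"
      coefficients:
        g0: -1.0
        gF: 8.0
        kF: 0.33
        gT: 0.3
        gT2: -0.3
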
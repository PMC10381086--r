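id: tarling2006
label: "Tarling et al. (2006) stage/length/temperature intermoult period"
type: empirical
citation: >
  Tarling GA, Shreeve RS, Hirst AG, Atkinson A, Pond DW, Murphy EJ,
  Watkins JL (2006) Natural growth rates in Antarctic krill (Euphausia
  superba): I. Improving methodology and predicting intermolt period.
  Limnology and Oceanography 51:959-972.
calibration:
  region: "Scotia Sea, South Georgia, northern Antarctic Peninsula"
  season: "austral summer"
  temperature_range_c: [-1.0, 5.0]
  chl_range: "not food-dependent (IMP model)"
  food_proxy: "none"
functions:
  # Intermoult period as the reciprocal of a moulting rate (hyperbolic in
  # its drivers): imp = 1 / rate.
  # juvenile:      rate = r0 + rcurv * (T - rcentre)^2   (no length effect)
  # adult female:  rate = r0 + rL * L + rT * T + rT2 * T^2
  imp:
    juvenile:
      citation: "Tarling et al. (2006), juvenile IMP fit"
      units: "days; T degC"
      coefficients:
        r0: 0.107
        rcentre: 3.0
        rcurv: 0.002
    "adult female":
      citation: "Tarling et al. (2006), adult-female IMP fit"
      units: "days; T degC, L mm"
      coefficients:
        r0: 0.135
        rL: -0.001
        rT: 0.003
        rT2: -0.003
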
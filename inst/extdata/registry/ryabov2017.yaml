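id: ryabov2017
label: "Ryabov et al. (2017) energy-partitioning growth model"
type: mechanistic
citation: >
  Ryabov AB, de Roos AM, Meyer B, Kawaguchi S, Blasius B (2017)
  Competition-induced starvation drives large-scale population cycles in
  Antarctic krill. Nature Ecology & Evolution 1:0177.
calibration:
  region: "Western Antarctic Peninsula (Palmer LTER in-situ chlorophyll)"
  season: "full year with winter metabolic switch"
  temperature_range_c: [-2.0, 3.0]
  chl_range: "in-situ, modest seasonal peaks (<2 mg m-3)"
  food_proxy: "chlorophyll a (Holling type II, low half-saturation)"
functions:
  # Energy intake allocated to metabolism first, residual to somatic
  # growth; Holling II uptake with a low half-saturation reflecting the
  # in-situ calibration data:
  #   dL/dt = arrh(T) * (intake_coef * f - metab_coef * w * L)
  # where w is the winter metabolic switch factor.
  growth:
    "all krill":
      citation: "Ryabov et al. (2017), energy partitioning rates"
      units: >
        intake_coef mm d-1; metab_coef d-1; half_saturation mg chl m-3;
        arrhenius_temp K; ref_temp_c degC
      coefficients:
        intake_coef: 0.34
        metab_coef: 0.004
        half_saturation: 0.5
        arrhenius_temp: 5000
        ref_temp_c: 0
        winter_factor: 0.6
winter_window: ["04-16", "10-31"]
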
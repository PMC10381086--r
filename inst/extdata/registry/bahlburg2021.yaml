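id: bahlburg2021
label: "Bahlburg et al. (2021) photoperiod-dependent DEB growth model"
type: mechanistic
citation: >
  Bahlburg D, Meyer B, Berger U (2021) The impact of seasonal regulation
  of metabolism on the life history of Antarctic krill. Ecological
  Modelling 442:109427.
calibration:
  region: "Western Antarctic Peninsula (in-situ forcing)"
  season: "full year, photoperiod-regulated metabolism"
  temperature_range_c: [-2.0, 3.0]
  chl_range: "in-situ, with months of daily chlorophyll a >2 mg m-3"
  food_proxy: "chlorophyll a (Holling type II)"
functions:
  # DEBkiss budget as jager2015 with a day-length scaling (derived from
  # the photoperiod-activity experiments of Piccolin et al. 2018) applied
  # multiplicatively to BOTH ingestion/assimilation and maintenance:
  #   s(P) = photoperiod_min_scale + (1 - photoperiod_min_scale) * P / 24
  growth:
    "all krill":
      citation: "Bahlburg et al. (2021), DEBkiss parameter set"
      units: >
        shape -; kappa -; assim_max mg d-1 mm-2; maint_rate mg d-1 mm-3;
        half_saturation mg chl m-3; arrhenius_temp K; ref_temp_c degC;
        photoperiod_min_scale -
      coefficients:
        shape: 0.2
        kappa: 0.8
        assim_max: 0.1125
        maint_rate: 0.0075
        half_saturation: 2.0
        arrhenius_temp: 6400
        ref_temp_c: 0
        photoperiod_min_scale: 0.5
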
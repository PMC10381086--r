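id: jager2015
label: "Jager & Ravagnan (2015) simplified DEB growth model"
type: mechanistic
citation: >
  Jager T, Ravagnan E (2015) Parsimonious modeling of an individual's
  energy budget: krill as a case study. Ecological Modelling 303:114-120.
calibration:
  region: "laboratory / literature compilation"
  season: "full year (no seasonal physiology)"
  temperature_range_c: [-2.0, 5.0]
  chl_range: "unlimited food assumed in the original validation"
  food_proxy: >
    none originally; scaled here by the Holling type II response of
    Bahlburg et al. (2021)
functions:
  # DEBkiss somatic budget on volumetric length Lv = shape * L:
  #   assimilation JA = f * assim_max * Lv^2    (f: Holling type II)
  #   maintenance  JS = maint_rate * Lv^3
  #   dLv/dt = arrh(T) * (kappa * JA - JS) / (3 * Lv^2)
  # Growth ceases where kappa*assimilation balances maintenance
  # (~60 mm physical length at f = 1).
  growth:
    "all krill":
      citation: "Jager & Ravagnan (2015), DEBkiss parameter set"
      units: >
        shape -; kappa -; assim_max mg d-1 mm-2; maint_rate mg d-1 mm-3;
        half_saturation mg chl m-3; arrhenius_temp K; ref_temp_c degC
      coefficients:
        shape: 0.2
        kappa: 0.8
        assim_max: 0.18
        maint_rate: 0.012
        half_saturation: 2.0
        arrhenius_temp: 6400
        ref_temp_c: 0
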
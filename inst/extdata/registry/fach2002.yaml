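id: fach2002
label: "Fach et al. (2002) bioenergetic growth model"
type: mechanistic
citation: >
  Fach BA, Hofmann EE, Murphy EJ (2002) Modeling studies of Antarctic
  krill Euphausia superba survival during transport across the Scotia
  Sea. Marine Ecology Progress Series 231:187-203.
calibration:
  region: "Scotia Sea transport pathways (model-derived forcing)"
  season: "full year"
  temperature_range_c: [-2.0, 4.0]
  chl_range: "model-derived chlorophyll a and heterotrophic carbon"
  food_proxy: "particulate organic carbon (chl a x 50); ice algae set to 0"
functions:
  # Same structure as hofmann2000 with a markedly weaker temperature
  # dependence of metabolism (documented by the original authors).
  growth:
    "all krill":
      citation: "Fach et al. (2002), energy budget rates"
      units: "ingest_slope mm d-1 per mg C m-3; metab_rate d-1; cap mm d-1"
      coefficients:
        ingest_slope: 0.0042
        metab_rate: 0.004
        q10: 1.3
        cap: 0.25
        winter_factor: 0.5
winter_window: ["04-16", "10-31"]
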
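id: hofmann2000
label: "Hofmann & Lascara (2000) bioenergetic growth model"
type: mechanistic
citation: >
  Hofmann EE, Lascara CM (2000) Modeling the growth dynamics of Antarctic
  krill Euphausia superba. Marine Ecology Progress Series 194:219-231.
calibration:
  region: "Western Antarctic Peninsula"
  season: "full year (regional model output forcing)"
  temperature_range_c: [-2.0, 3.0]
  chl_range: "model-derived; >1 mg m-3 for more than 3 months per year"
  food_proxy: "particulate organic carbon (chl a x 50)"
functions:
  # Clearance-rate feeding on POC with assimilation, temperature-dependent
  # (Q10) metabolic losses mapped through the length-mass coupling.
  # Daily length change (mm d-1), capped at `cap`:
  #   dL/dt = min(ingest_slope * POC - metab_rate * L * Q10^(T/10) * w, cap)
  # where w is the winter metabolic switch factor.
  growth:
    "all krill":
      citation: "Hofmann & Lascara (2000), energy budget rates"
      units: "ingest_slope mm d-1 per mg C m-3; metab_rate d-1; cap mm d-1"
      coefficients:
        ingest_slope: 0.0044
        metab_rate: 0.004615
        q10: 2.5
        cap: 0.25
        winter_factor: 0.5
winter_window: ["04-16", "10-31"]
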
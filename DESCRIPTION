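Package: krillgrowth
Title: Intercomparison of Antarctic Krill Growth Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements eight published growth models for Antarctic krill
    (Euphausia superba) -- three empirical (instantaneous growth rate and
    two moult-based composites) and five mechanistic (bioenergetic and
    Dynamic Energy Budget) -- behind a common model contract, together with
    the shared simulation protocol (daily forcing, 1 November to 15 April,
    ice masking, stage switching) and intercomparison analytics:
    temperature-by-chlorophyll response surfaces, trajectory ensembles,
    required-chlorophyll inversion and cross-model divergence maps. Includes
    a synthetic seasonal forcing generator and a day-of-year climatology
    reader for gridded sea-surface temperature and chlorophyll a data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
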
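Package: luccarbon
Title: Land-Use Change Carbon Accounting with Design-Based Area Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for national-scale terrestrial carbon budgeting driven by
    land-use change. Implements design-based adjustment of mapped land-change
    areas from stratified accuracy-assessment error matrices, with variances,
    confidence intervals and accuracy summaries; an annual-time-step carbon
    book-keeping model in which harvest, clearing and afforestation events
    create cohorts whose wood-product pools (1/10/100-year), slash, soil and
    regrowth generate yearly release and uptake; a scenario engine for building
    and perturbing land-use rate series, including a parameterised template for
    the country of Georgia; and synthetic-data generators for validating the
    estimators and the simulator by Monte Carlo.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
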
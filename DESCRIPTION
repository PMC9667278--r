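Package: sedidose
Title: External Dose and Lifetime Cancer Risk from Contaminated Sediment Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose and risk assessment for sites contaminated with layered
    gamma-emitting sediments, such as a dried-out dredging pond at a nuclear
    power plant under decommissioning. Builds conservative activity depth
    profiles (Bq/kg wet weight) from sediment core samples, converts them to
    age- and sex-specific equivalent doses using cumulative-depth external
    dose-rate coefficient tables (FGR-15 style), combines these into the
    ICRP effective dose, and evaluates lifetime attributable risk (LAR) of
    cancer via survival-weighted integration of excess-rate models (BEIR
    VII/EPA form). Remediation scenarios (removing sediment layers or adding
    clean soil cover) are swept and searched for the smallest action meeting
    an annual dose limit such as the Swedish 0.1 mSv free-release criterion.
    Ships a synthetic-data generator with closed-form oracles so the whole
    pipeline is testable without external coefficient tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
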
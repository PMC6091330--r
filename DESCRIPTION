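Package: mmstaging
Title: Multiple Myeloma Staging from IMPeTUs PET/CT Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for staging newly diagnosed multiple myeloma from
    standardized FDG-PET/CT reports. Parses IMPeTUs (Italian Myeloma
    criteria for PET USe) descriptor strings into structured records,
    assigns Durie-Salmon (DSS), Revised International Staging System
    (RISS) and Durie-Salmon Plus stages from laboratory panels and
    imaging descriptors, quantifies between-system concordance with
    weighted Cohen's kappa, and runs Kaplan-Meier, log-rank and Cox
    proportional-hazards survival analyses on staged cohorts. Ships a
    33-patient reference cohort and a synthetic-cohort generator with a
    proportional-hazards survival model so every analysis step is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
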
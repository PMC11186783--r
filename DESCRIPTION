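Package: o3burden
Title: Source-Apportioned Ozone-Attributable Mortality Burden Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Health-impact assessment of ground-level ozone with source
    apportionment. Converts source-tagged daily maximum 8-hour average (MDA8)
    ozone fields, gridded population and weekly all-cause mortality into
    ozone-attributable mortality (attributable fraction and number) under a
    log-linear exposure-response model, apportioned by geographic emission
    source, with empirical confidence intervals propagated from the
    exposure-response coefficient. Includes a toy tagged-photochemistry box
    model with NOx/VOC-regime-based attribution, MDA8 computation with the
    regulatory availability filter, FAIRMODE-style model evaluation metrics
    (NMB, NRMSE, MQI), and a synthetic-data generator emulating the structure
    of European regional mortality and ozone data so the full pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
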
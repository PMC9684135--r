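Package: firethresh
Title: Vapour-Pressure-Deficit Thresholds for Forest Fire Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits binomial-logit models of daily fire occurrence against
    daily maximum vapour pressure deficit (VPD), extracts the VPD value at
    which the probability of fire reaches 50% together with delta-method
    uncertainty and ROC-based diagnostics, and projects the change in annual
    threshold-exceedance days under bias-corrected (empirical quantile
    mapping) future climate, including population and forest-carbon
    exposure rasters. Ships a seeded synthetic-data generator emulating
    reanalysis-like climate fields, burned-area records with burn history,
    distorted GCM-like series, and fine-resolution density rasters, so the
    whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
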
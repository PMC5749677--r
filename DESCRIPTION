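Package: firecal
Title: Calibration and Verification of Gridded Fire-Danger Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive area-specific fire-danger class thresholds from a
    daily Fire Weather Index (FWI) climatology and to verify them against
    gridded burned-area observations. Includes NetCDF import/stacking
    utilities for daily gridded fields, polygon masking and cropping,
    per-cell percentile climatologies, fire-season selection, the
    fire-intensity transform with geometric class progression used to place
    danger-class boundaries, contingency-table verification (probability of
    detection, ROC/AUC), and a synthetic-data generator emulating
    reanalysis-like FWI cubes and satellite-like burned-area cubes so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    sp,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
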
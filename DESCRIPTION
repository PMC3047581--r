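Package: lrequant
Title: Absolute Real-Time qPCR Quantification by Linear Regression of Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standard-curve-free absolute quantification of real-time qPCR
    targets from raw SYBR Green I fluorescence profiles using linear
    regression of efficiency (LRE). Per-cycle amplification efficiency is
    regressed against cycle fluorescence to estimate maximal efficiency
    (E_max), its loss rate (Delta E) and plateau fluorescence (F_max), from
    which the initial target fluorescence (F_0) is back-calculated and
    converted to an absolute molecule count per reaction via an optical
    calibration factor. Includes automated analysis-window selection,
    technical-replicate averaging and variance statistics, kinetic-anomaly
    diagnostics (plateau drift, profile collapse, arcing), import/export of
    plate templates, a versioned project store, a synthetic-profile
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
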
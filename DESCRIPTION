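Package: vesselmass
Title: Estimate Vessel Displacement from Length Overall for Whale-Strike
    Risk Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Converts a vessel's length overall (LOA) and type into an
    estimate of its displacement (total mass), the input most often
    missing when feeding biophysical whale-ship collision models.
    Implements the deadweight-tonnage to displacement conversion
    strategies used to assemble an 873-vessel training set (deadweight
    coefficient interpolation, linear and power conversion equations,
    unit dialects, net-weight correction), fits the log-log regression of
    displacement on LOA with vessel type as an interaction, ships the
    fitted per-type power-law coefficients as loadable data, generates
    synthetic fleets with the statistical structure of the training
    sample, and provides a harness that feeds estimated masses to a
    pluggable strike-lethality model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
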
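Package: gardenring
Title: Tree-Ring Drought Response Analysis for Common-Garden Provenance Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dendrochronological analysis of provenance trials:
    reading Tucson/RWL and long-form ring-width data, cross-dating statistics
    (interseries correlations and the expressed population signal), detrending
    with a single common smoothing spline and reversed standardization so that
    absolute growth differences between populations are preserved, Lloret
    drought resistance/recovery/resilience indices with shared reference
    windows, Hargreaves reference evapotranspiration and climatic moisture
    deficit from daily weather, mixed-model regional trait estimation (BLUEs
    with Tukey-adjusted letter groups), Spearman/Holm trait-climate
    association screening, climate PCA, and a synthetic-data generator that
    emulates a randomized complete block provenance trial with drought shocks
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    grid,
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    multcomp,
    withr
Config/testthat/edition: 3
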
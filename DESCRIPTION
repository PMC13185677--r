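Package: broodr
Title: Reproductive Phenology of Brooding Intertidal Invertebrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population-level reproductive phenology of brooding
    intertidal invertebrates (such as the acorn barnacle Semibalanus
    balanoides) from repeated embryo-stage survey counts and intertidal
    temperature time series. Survey proportions are scaled, split at peak
    brooding, and fit with quasi-binomial logistic regressions to estimate the
    fertilization midpoint (F50), the larval-release midpoint (LR50), and
    brooding duration. Temperature series are regularized to an hourly grid,
    low-pass filtered with the oceanographic PL64 filter (33-h half-amplitude
    cutoff), and summarized over fall windows to build temperature and
    phenology anomalies. Two inference models relate fall temperature
    anomalies to F50 anomalies and log brooding duration to mean brooding
    temperature. A seeded synthetic-study generator with temperature-dependent
    embryonic development supports parameter-recovery testing of the whole
    pipeline.
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
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
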
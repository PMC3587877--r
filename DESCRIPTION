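Package: eegdepth
Title: Quantitative EEG Characteristics and Feature-Vector Selection for
    Depth-of-Anesthesia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts nineteen quantitative EEG characteristics (spectral,
    burst-suppression, bispectral and entropy based) from single-channel EEG,
    classifies epochs into four anesthesia states (awake, light, deep,
    isoelectric) with a Gaussian class-conditional classifier under stratified
    cross-validation, and searches feature-vector combinations of dimension
    two to five with a genetic algorithm to find the subsets with maximal
    sensitivity, specificity and total accuracy. Includes a labelled
    synthetic anesthesia-EEG generator so the full pipeline is testable
    without patient data, plus EDF and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
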
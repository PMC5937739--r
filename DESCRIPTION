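Package: hybridbci
Title: Hybrid EEG-fNIRS Brain-Computer Interface Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for eyes-closed hybrid
    EEG-fNIRS brain-computer interfaces driven by mental arithmetic versus
    baseline relaxation over frontal cortex. Provides a synthetic session
    generator with a Beer-Lambert forward model and known ground truth,
    preprocessing (decimation, zero-phase Butterworth filtering, blind
    source separation based ocular artifact removal, modified Beer-Lambert
    conversion), signed r-squared band selection, common spatial patterns
    with ratio-of-medians component scoring, shrinkage LDA classification
    with meta-classifier fusion of EEG and hemoglobin channels, nested
    cross-validation, information transfer rates, and nonparametric group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
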
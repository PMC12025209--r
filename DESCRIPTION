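Package: wristemg
Title: Wrist Movement Recognition and Muscle Force Estimation from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for myoelectric control of wrist
    rehabilitation: time-domain feature extraction (MAV, RMS, VAR, ZC, WL)
    from 8-channel surface electromyography, ReliefF feature weighting with
    top-2-per-channel selection, a two-hidden-layer backpropagation neural
    network classifier for seven wrist movements, a sliding majority-of-5
    voting filter with a five-consecutive-identical command trigger, and
    static (MAV-to-load linear) and dynamic (gravity plus inertia) muscle
    force estimation models with RMSE evaluation. Includes a seeded synthetic
    sEMG generator emulating an 8-channel armband so the whole pipeline is
    testable without hardware.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
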
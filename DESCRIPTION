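Package: eggwave
Title: Artifact Rejection and Spectral Analysis for Electrogastrography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning and analysing cutaneous electrogastrogram
    (EGG) recordings. Implements a linear minimum mean-squared error
    (LMMSE) motion-artifact estimator built from locally estimated mean
    and variance statistics, short-time Fourier spectral features of the
    gastric slow wave (band power, normalized power, dominant frequency,
    percent normal 2-4 cpm activity, signal-to-noise ratio), electrode
    re-referencing and best-pair selection, an antral manometry motility
    index with EGG-manometry regression statistics, event-aligned
    averaging for ambulatory recordings, and a seeded synthetic-data
    generator that provides ground truth for every stage of the
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
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
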
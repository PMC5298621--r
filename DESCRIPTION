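Package: fbgbp
Title: Cuffless Blood Pressure Calibration from Fiber Bragg Grating Pulse Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end calculation pipeline for blood pressure estimation
    with a fiber Bragg grating (FBG) strain sensor interrogated by a
    Mach-Zehnder interferometer. Demodulates three-phase detector outputs
    into an interferometric phase and Bragg-wavelength shift, band-pass
    filters the resulting acceleration-pulse-wave signal, segments and
    ensemble-averages heart beats into normalized waveforms, and fits PLS1
    calibration curves (NIPALS, leave-one-out PRESS with sequential F-test
    factor selection) that map beat shape to cuff-reference blood pressure.
    Includes a synthetic-subject generator so the whole pipeline, including
    the comparison of individual versus pooled calibration curves, can be
    exercised and validated without sensor hardware.
License: MIT
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
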
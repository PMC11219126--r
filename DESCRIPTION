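Package: gazefilt
Title: Low-Pass Filter Comparison for High-Rate Eye-Tracking Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to design and compare the zero-phase low-pass filters
    commonly applied to 1000 Hz video-oculography gaze recordings:
    Savitzky-Golay smoothing, Butterworth (IIR) and windowed-sinc (FIR)
    filters. Frequency responses are computed directly from coefficients
    and estimated empirically by the FFT ratio method; fixation segments
    are selected by a saccade-velocity screen, converted to averaged
    amplitude spectra (polynomial detrend, Hanning window, block
    averaging), and the effect of filtering on temporal autocorrelation
    is quantified with Fisher-Z transforms, Friedman tests and
    Tukey-style pairwise rank comparisons. A seeded synthetic gaze
    generator emulates fixation noise and saccades so the whole analysis
    is reproducible without recordings.
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
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
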
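Package: respiradar
Title: Contactless Respiratory-Rate Estimation from Continuous-Wave Doppler Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for contactless monitoring of respiratory rate variability
    with a continuous-wave (CW) Doppler radar. Provides a physics-based
    simulator of quadrature (I/Q) radar baseband signals produced by
    millimetre-scale chest-wall displacement, an instantaneous
    respiratory-rate pipeline (zero-phase low-pass filtering, peak detection,
    peak-interval frequency, a signal-quality index used to reject abnormal
    intervals, and uniform resampling to breaths per minute), and the
    validation statistics used to compare radar against a displacement
    reference: Bland-Altman limits of agreement, Pearson correlation, RMSE,
    MAPE, and Kruskal-Wallis with Dunn post-hoc comparisons across anesthesia
    protocol levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
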
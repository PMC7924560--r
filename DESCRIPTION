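Package: fetalMPI
Title: Automated Fetal Left-Ventricular Myocardial Performance Index from
    Pulsed-Doppler Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures fetal left-ventricular cardiac time intervals (filling
    time, ejection time, isovolumetric contraction and relaxation times) and
    the derived myocardial performance indices (Tei index and K-index) from
    pulsed-Doppler waveform traces. Provides image-to-envelope conversion of
    grayscale Doppler trace images, zero-phase Butterworth low-pass filtering,
    automatic multiscale-based peak detection (AMPD) of the dominant A-wave,
    windowed landmark search for interval boundaries, intraclass correlation
    reliability statistics, and a synthetic waveform generator with exact
    ground-truth landmarks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
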
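Package: lvadsound
Title: Acoustic Analysis of Continuous-Flow LVAD Sound for Detecting Aortic Regurgitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the sound of continuous-flow left ventricular
    assist devices (LVADs) recorded with an electronic stethoscope. Provides a
    synthetic pump-sound generator with planted ground truth (harmonic stack at
    the rotational frequency, cardiac frequency modulation, respiratory
    amplitude modulation, intermittent-low-speed protocol, band-limited noise),
    a Gabor wavelet time-frequency analyzer with amplitude normalization to
    arbitrary units, harmonic ridge tracking and intermittent-low-speed
    segmentation, extraction of 19 acoustic features per recording, and a
    filter-plus-wrapper feature-selection procedure with a multi-classifier
    benchmark (accuracy, AUC, true positive and true negative rates) for
    detecting significant aortic regurgitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
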
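Package: sdleeg
Title: Scale-Dependent Lyapunov Exponent Analysis of EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Distinguishes epileptiform discharges from normal background
    electroencephalogram (EEG) using the scale-dependent Lyapunov exponent
    (SDLE), a multiscale complexity measure estimated from delay-embedded
    phase-space trajectories. Provides EDF input/output and epoching,
    band-pass/notch preprocessing with strongest-channel selection, spectral
    band-energy features, shell-based error-growth and SDLE estimation with
    scaling-law fitting, a seeded synthetic generator of normal and
    epileptiform EEG epochs, and random-forest/support-vector-machine
    classification with sensitivity, specificity, accuracy and ROC/AUC
    reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    e1071,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
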
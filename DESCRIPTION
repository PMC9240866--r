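Package: multisitefc
Title: Multi-Site Resting-State Functional Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for classifying patients and controls from multi-centre
    resting-state fMRI functional connectivity. Provides a synthetic
    multi-site cohort simulator with known discriminative structure,
    time-series conditioning (framewise-displacement motion QC,
    winsorization, detrending, bandpass or wavelet-subband filtering,
    nuisance regression), Fisher-Z correlation featurization with per-site
    connection-wise Z-score harmonization, linear support-vector
    classification under intra-centre, pooled, leave-one-site-out and
    transfer learning-curve cross-validation, permutation significance
    testing, and post-hoc analyses of discriminative connections,
    site-effect ANOVAs and confounder logistic regressions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    kernlab,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
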
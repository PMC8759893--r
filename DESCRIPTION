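Package: swetools
Title: Shear-Wave Elastography Simulation and Speed-Estimation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates acoustic-radiation-force shear-wave displacement fields in
    elastic and Voigt-viscoelastic tissue-mimicking phantoms and estimates the
    shear-wave speed by four methods: sample-resolution time-to-peak (SPM),
    sub-sample time-to-peak with spline upsampling and parabolic refinement
    (TDPM), cross-correlation time-shift (TSPM), and a Radon-sum group-velocity
    search. Includes Voigt-model dispersion and parameter fitting, speed-to-
    Young's-modulus conversion, Monte-Carlo benchmarking of estimator bias and
    random error, and the agreement and diagnostic statistics used in
    elastography reader studies (ICC, repeated-measure summaries, ROC/AUC,
    Youden threshold, 2x2 metrics). Fields travel in an HDF5 container; a small
    command-line interface wraps the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    rhdf5,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
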
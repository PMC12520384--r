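Package: cardiorespvp
Title: Virtual Cardio-Respiratory Populations for Wearable-to-Clinical
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates virtual populations of healthy and
    cardio-respiratory-diseased subjects with a closed-loop 0D
    (lumped-parameter) cardio-respiratory model, and trains Gaussian-process
    regression surrogates that predict in-hospital variables (central venous
    pressure, stroke volume, cardiac output, ejection fraction, arterial
    blood gases) from wearable-derivable signals (heart rate, central blood
    pressures, arterial oxygen saturation). Includes scrambled Sobol'
    quasi-Monte-Carlo sampling of physiological parameter spaces,
    derivative-based local and variance-based global sensitivity analysis,
    physiological range filtering with multi-label disease classification,
    and propagation of wearable acquisition errors through the trained
    regressors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    arrow,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
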
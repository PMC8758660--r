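Package: kneebis
Title: Personalized Bioimpedance Modelling of the Human Knee
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-specific modelling of tetrapolar bioimpedance
    spectra of the human knee. Tissues are described by multi-dispersion
    Cole-Cole effective dielectric permittivities (with an anisotropic
    skeletal-muscle tensor identified by constrained optimization), the knee by
    a five-layer cylindrical geometry personalized from sex, body-mass index
    and knee circumference, and the electric field by a quasi-static
    complex-potential finite-element solver. A seven-parameter Nelder-Mead
    personalization fits the model to measured impedance-magnitude spectra,
    and a synthetic-cohort generator provides reproducible validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
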
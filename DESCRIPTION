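Package: frpe
Title: Fibril-Reinforced Poroelastic Modeling of Cartilage Indentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inverse analysis of articular cartilage
    indentation with a fibril-reinforced poroelastic (FRPE) material model.
    Provides an axisymmetric biphasic (displacement-pressure) finite-element
    solver for plane-ended indentation and confined compression, extraction of
    elastic (equilibrium and instantaneous) and dynamic viscoelastic (dynamic
    modulus, phase difference) properties from multi-step stress-relaxation
    and sinusoidal indentation records with the Hayes thickness correction,
    inverse identification of the five FRPE constituent parameters from
    stress-relaxation data, a synthetic cohort generator emulating an
    osteoarthritis grading study, and knee-clustered descriptive statistics
    with bootstrap group contrasts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
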
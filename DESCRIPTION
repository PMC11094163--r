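Package: pdtsim
Title: Digital Simulation of Programmed Dual-Wavelength Photodynamic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico optimisation of programmed dual-wavelength
    photodynamic therapy (PDT) with light-responsive photosensitizer-loaded
    micelles. Provides a synthetic factorial cell-viability dataset generator
    built on a Hill-by-light-dose ground-truth response surface, a
    single-hidden-layer tanh neural-network surrogate of viability versus
    treatment factors with permutation factor importance, a calibrated
    agent-based simulation comparing sequential 405-580 and 580-405 nm
    lighting protocols, photophysics and formulation arithmetic (degree of
    polymerization from NMR integrals, loading and encapsulation efficiency,
    first-order photosensitizer release kinetics, singlet-oxygen generation
    fold, fluence and generator-power dosimetry), tumor-volume and
    Bland-Altman method-agreement utilities, and an end-to-end reproducible
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    nnet,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
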
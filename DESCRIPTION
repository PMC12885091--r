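Package: specklesim
Title: Simulation and Estimation of Deep-Tissue Blood Flow from Diffuse
    Speckle Contrast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of diffuse speckle visibility curves from the
    semi-infinite solution of the correlation diffusion equation, and
    estimation of the blood flow index (BFI) from such curves by four
    methods: multi-exposure speckle imaging (MESI, joint non-linear fit of
    flow and the speckle averaging factor), single-exposure look-up-table
    inversion, speckle contrast optical spectroscopy (SCOS), and speckle
    plethysmography (SPG). Includes multiplicative measurement-noise
    injection, a synthetic cardiac-like pulsatile flow generator, error
    metrics, and Monte-Carlo experiment drivers that compare the robustness
    of single- versus multi-exposure estimators under speckle-averaging
    mismatch, noise, pulsatile flow, and reduced exposure sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
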
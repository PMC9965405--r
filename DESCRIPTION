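Package: relkin
Title: Release Kinetics, Diffusion and Photostability Analysis for
    Drug-Loaded Electrospun Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing in-vitro drug-release experiments on
    fibrous (electrospun) membranes. Fits and compares the four classical
    dissolution models (zero-order, Higuchi, Korsmeyer-Peppas and the
    log10 Gompertz sigmoid) by bounded nonlinear least squares with a
    deterministic initialisation rule; estimates Fickian diffusion
    coefficients from the short-time (square-root) and long-time
    (single-exponential) plane-sheet asymptotics; models photolytic loss
    of the active compound as a power law in irradiation time; and
    provides mean-line surface-roughness metrics (Ra, RMS), gravimetric
    liquid-retention and contact-angle summaries, and MTT viability
    normalisation. Seeded synthetic-data generators emulate every input
    the pipeline consumes, including an exact plane-sheet eigenfunction
    series used as the diffusion oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    png,
    tiff
Config/testthat/edition: 3
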
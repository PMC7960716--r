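Package: smfdyn
Title: Single-Molecule Fluorescence Analysis of Receptor Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying protein conformational dynamics from
    single-molecule fluorescence experiments: ALEX smFRET burst detection,
    gamma/background/crosstalk corrections, FRET-efficiency histogram
    decomposition into Gaussian mixtures with AIC model selection and
    bootstrap errors, multi-exponential fluorescence lifetime and
    polarization anisotropy decay fitting with parametric bootstrap,
    PET-FCS correlation analysis (multi-tau correlator, diffusion plus
    triplet plus quenching blinking model, global fits with shared
    parameters), and post-processing of molecular-dynamics distance
    trajectories into quench-state transition statistics. Every analysis
    path has a seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
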
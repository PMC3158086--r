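Package: nodulePDT
Title: High-Content Image Analysis of 3D Tumor Nodule Cultures Under
    Photodynamic Therapy
Version: 0.1.0
Authors@R:
    person("Nodule", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for high-throughput, high-content fluorescence image
    analysis of adherent 3D ovarian-cancer nodule cultures treated with
    photodynamic or chemo-therapy. Implements well-level live/dead
    viability scoring with automatic histogram-mode background
    subtraction and no-treatment normalization, per-nodule Otsu
    segmentation and morphometry, power-law fits of live:dead ratio
    against nodule volume, boundary-referenced penetration-depth
    estimation, ratiometric SNARF band-ratio pH imaging from
    hyperspectral cubes, PI/apoTRACE apoptosis co-localization maps, and
    spectral fluence-rate correction between treatment wavelengths. A
    seeded synthetic renderer produces ground-truth-annotated nodule
    field imagery (acidic cores, periphery- versus core-localized
    killing, dose- and irradiance-dependent survival, Poisson plus
    Gaussian camera noise) for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
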
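Package: dbimtwist
Title: Microwave Tomography for Brain Stroke Detection with DBIM-TwIST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained microwave tomography pipeline for brain stroke
    detection and classification. Builds dispersive (single-pole Debye) head
    phantoms immersed in a glycerol-water matching medium, simulates
    multistatic antenna-array measurements with a 2D transverse-magnetic
    finite-difference time-domain (FDTD) solver with convolutional
    perfectly-matched-layer boundaries, calibrates "target"/"no target"
    measurement pairs against a simulated baseline, and reconstructs
    quantitative complex-permittivity maps with the distorted Born iterative
    method using a two-step iterative shrinkage/thresholding (TwIST) inner
    solver with multi-frequency hopping. Includes target detection and
    haemorrhagic/ischaemic stroke classification from the reconstructed maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
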
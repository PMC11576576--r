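Package: pcctSPR
Title: Virtual Photon-Counting CT Study of Proton Stopping-Power Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained virtual study of proton stopping-power-ratio (SPR)
    estimation from photon-counting computed tomography (PCCT) of the head.
    Provides tissue physics (electron density, mean ionization energy,
    Bethe-Bloch stopping-power ratios, linear attenuation, Hounsfield units),
    procedural digital head phantoms with known per-voxel compositions, a
    simplified energy-binned CT simulator with projection-space
    maximum-likelihood two-material decomposition and filtered back-projection,
    virtual monoenergetic image synthesis, two physics-based SPR estimators
    (stoichiometric HU-to-SPR calibration and a VMI-pair effective-atomic-number
    method), a small U-Net image-to-image regression model trained with
    L1/MSE/perceptual losses, and region-of-interest error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite, RNifti
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
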
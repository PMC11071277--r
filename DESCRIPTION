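Package: cntomo
Title: Unsupervised Coordinate-Network Reconstruction for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Missing-wedge-compensated tomographic reconstruction for
    cryo-electron tomography (cryoET). Fits a sinusoidal coordinate network
    directly to the projection images of a tilt series (no pretraining),
    reconstructs large tomograms by fitting y-axis subvolumes with learned
    initialization, and evaluates reconstructions against a weighted
    back-projection baseline using PSNR, SSIM, VIF, global Fourier shell
    correlation (FSC), and a directional FSC restricted to the missing-data
    region of Fourier space. Includes a phantom simulator (hollow spheres and
    mixed geometric shapes in slab geometry), a differentiable parallel-beam
    projector, MRC2014/TIFF/tlt input and output, and a command-line
    interface for the full simulate-project-reconstruct-evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
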
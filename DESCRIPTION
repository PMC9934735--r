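Package: gcdiff
Title: Geometry-Complete Denoising Diffusion for 3D Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An SE(3)-equivariant joint denoising diffusion model over 3D atom
    coordinates and categorical atom features, with a chirality-aware
    frame-based denoising network trained by noise prediction. Provides
    variance-preserving noise schedules on the zero-centre-of-mass subspace,
    property-conditional generation, diffusion-based molecule optimization,
    a valency-based molecule-quality metric suite (atom/molecule stability,
    validity, uniqueness, novelty, energy ratio), XYZ/SDF molecule I/O, and a
    synthetic template-based fixture generator so every stage can be trained
    and evaluated on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
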
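Package: lanternimg
Title: Single-Pixel Computational Imaging Through a Photonic Lantern
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end simulation and reconstruction for single-pixel
    imaging through a multicore-fibre photonic lantern. Builds the ordered
    Bessel eigenmodes of a circular ideal-mirror waveguide, synthesizes
    multimode speckle patterns as random orthonormal coherent superpositions
    of those modes, forms single-pixel measurements of a test object, and
    reconstructs the object by sparsity-averaging reweighted-l1 analysis
    (SARA): a positivity- and l2-ball-constrained weighted l1 minimisation
    over a nine-basis wavelet dictionary, solved with a primal-dual
    forward-backward proximal algorithm. A classical ghost-imaging
    correlation estimator is included as a prior-free baseline, together
    with test phantoms (knife edge, offset cross, dots, three-bar groups)
    and pattern/reconstruction quality metrics (overlap integral,
    reconstruction SNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
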
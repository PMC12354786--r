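Package: wallmech
Title: Fibrous-Network Tensile Mechanics of Plant Epidermal Cell Walls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of large-deformation tensile tests on plant epidermal
    cell layers and mechanistic models of the underlying cell-wall fibrous
    network. Provides smoothing-spline curve conditioning, tangent stiffness
    and incremental Poisson's ratio extraction, three-regime summary metrics
    (E1, E2, nu1, nu2), cyclic loading segmentation and recovery analysis; an
    affine isotropic fiber-network model; a five-beam diamond unit with beam
    bending and elastoplastic connector slip; plane-stress neo-Hookean and
    Yeoh plate responses with pressurized-shell side analyses; and a
    synthetic tensile-curve generator so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
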
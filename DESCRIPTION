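Package: corticofold
Title: Reaction-Diffusion Simulation of Cortical Folding on Triangulated Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates cortical gyrification as Gray-Scott morphogen
    dynamics on a closed triangulated surface, solved with linear (P1)
    finite elements for the Laplace-Beltrami operator and coupled to
    deformation of the surface along its vertex normals. The growing
    surface feeds back into the chemistry through a metric dilution
    term. Includes adaptive midpoint refinement of over-stretched
    triangles, discrete mean-curvature maps, curvature-based fold
    segmentation and counting, temporal fold-stability maps, ensemble
    reproducibility maps over noisy initial conditions, and an (F, k)
    phase-diagram sweep with regime classification (homogeneous /
    spot-like / stripe-like patterns, the analogues of lissencephaly,
    polymicrogyria and normal gyrification). ASCII OFF and PLY mesh
    input/output and a small command-line driver are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
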
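Package: turingkit
Title: Design, Simulation and Classification of Turing Reaction-Diffusion Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructive design of two-species polynomial reaction-diffusion
    kinetics whose Turing-unstable parameter set coincides with a user-chosen
    level-set region S(p) > 0. Provides the linear Turing analysis (stability
    conditions, nondimensional reduction, critical diffusion ratio, unstable
    wavenumber band, minimum domain length, dispersion relation, suprema of
    these quantities over parameter regions), constructors for cross, pure,
    phase-switching, cubic-augmented and arbitrary-steady-state kinetic
    families with a built-in self-verification oracle, spatiotemporal
    parameter heterogeneity including image-derived prepatterns, a
    method-of-lines solver on 1D intervals and 2D rectangles with zero-flux
    boundaries, and classification of the resulting patterns (mode counts,
    spots versus stripes, morphogen phase).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    deSolve,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
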
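Package: ringlink
Title: Conformational and Ionic-Atmosphere Analysis of Catenated Ring Polymer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular trajectories of two mechanically
    interlocked (catenated) ring polymers, such as DNA [2]-catenanes, together
    with their mobile counterions. Provides per-ring gyration-tensor shape
    descriptors (radius of gyration, relative shape anisotropy, asphericity,
    prolateness) with block-averaged uncertainties, center-of-mass effective
    potentials from the pair distribution of ring separations with multi-well
    minima detection and state assignment, separation-orientation kernel
    density maps, ion-DNA radial distribution functions, condensed-ion
    fractions, inter-ring contacts and divalent ion bridge detection, an
    analytic rigid-linked-ring insertion model with a Monte Carlo sampler
    constrained by the discrete Gauss linking number, and a synthetic
    catenane generator that emulates the statistical structure of atomistic
    trajectories for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
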
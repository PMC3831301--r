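Package: red3d
Title: Rotation Electron Diffraction Data Reduction
Version: 0.1.0
Authors@R:
    person("RED", "Maintainers", email = "red3d@example.org", role = c("aut", "cre"))
Description: Processing of three-dimensional rotation electron diffraction
    (RED / electron diffraction tomography) data: reading MRC frame stacks and
    plain-text experiment information files, correction of direct-beam drift by
    incremental cross-correlation, difference-of-Gaussians peak hunting,
    back-projection of diffraction spots onto the Ewald sphere and
    reconstruction of the three-dimensional reciprocal lattice, refinement of
    the tilt-axis azimuth, unit-cell determination by density clustering of
    difference vectors, adaptive indexing tolerant of lattice bending, and
    export of reflection intensities in SHELX HKLF4 format. A forward
    simulator of rotation-ED experiments (Ewald-sphere projection, rocking
    attenuation, Poisson noise, beam drift, 12-bit saturation) makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
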
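Package: dopmtools
Title: Dual-View Oblique Plane Microscopy Simulation, Reconstruction and
    PSF Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolkit for dual-view oblique plane microscopy
    (dOPM) of cleared tissue. Provides closed-form optical calculators for
    the remote-refocusing relay (magnification/refractive-index matching,
    correction-collar compensation, collection-NA overlap of tilted
    objective cones, diffraction-limit estimates), a seedable synthetic
    bead-phantom acquisition simulator, oblique-stack reconstruction
    (deskew/reslice for remote-refocus and stage scanning), bead-based
    two-view registration and fusion, and an automated 3D bead-PSF and
    optical-sectioning quantification pipeline with spatially binned
    resolution maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
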
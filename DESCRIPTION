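Package: vncmorph
Title: Quantification and Mechanical Modeling of Ventral Nerve Cord Condensation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tissue-scale morphodynamics of the
    Drosophila embryonic ventral nerve cord (VNC) during condensation.
    Provides windowed cross-correlation particle image velocimetry (PIV)
    with spatiotemporal Gaussian interpolation, flow-coherence statistics
    and kymographs, cell-track directionality summaries, elliptical-cylinder
    tissue morphometry and ellipse-fit eccentricity, collagen-IV intensity
    dynamics, photobleached-stripe displacement analysis, Hertz-model AFM
    force-curve fitting, and a reduced two-material core-plus-shell finite
    element model of surface-tension-driven condensation. A synthetic-data
    module generates every input with known ground truth so the whole
    pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
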
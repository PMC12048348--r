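Package: sedisloc
Title: Dislocation Analysis in Molecular Crystals from Scanning Electron
    Diffraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Low-dose, single-exposure characterization of individual
    dislocations in beam-sensitive molecular crystals from scanning
    electron diffraction (SED / 4D-STEM) data. Provides a calibrated
    four-dimensional dataset container with pattern centering, elliptical
    distortion correction and annular dark-field imaging; Bragg disc
    detection with sub-pixel refinement and virtual dark-field (VDF)
    reconstruction per diffraction vector; bend-contour centerline
    tracing and displacement metrology across a dislocation line;
    weighted nonlinear least-squares fitting of the azimuthal
    displacement model f(phi) = A*arctan(B*cos^2(phi - C)) with
    bootstrap confidence intervals; and derivation of the Burgers vector
    direction, invisibility set (g.B = 0), dislocation character,
    screw handedness and operative slip system. A ground-truthed
    synthetic 4D-data generator supports closed-loop validation of the
    whole pipeline at realistic electron doses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    png,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'acquisition.R'
    'dataset.R'
    'discs.R'
    'contour.R'
    'burgers.R'
    'crystal.R'
    'simulate.R'
    'pipeline.R'
    'cli.R'
    'sedisloc-package.R'
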
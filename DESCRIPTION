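Package: axistack
Title: Automated Triage of Transaxial Cardiovascular MR Anatomy Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments transaxial bright-blood cardiovascular magnetic
    resonance anatomy slices into nine anatomical classes, reassembles
    the slice stack into a calibrated three-dimensional thorax model by
    trilinear interpolation, derives body-surface-area indexed chamber
    volumes, left-ventricular mass, ascending aortic diameter and
    pleural fluid volume, and classifies each study against published
    abnormality cut-offs. Includes a synthetic thorax phantom generator
    with analytically known structure volumes so every pipeline stage
    is testable without patient data, plus the agreement statistics
    (Dice, Cohen's kappa, Wilson intervals, ROC) used to evaluate such
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
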
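Package: irisloc
Title: Robust Iris Boundary Localization with a Compensated Radial-Gradient Operator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage localization of the pupillary (inner) and limbic (outer)
    iris boundaries in eye images acquired in non-cooperative environments.
    Implements Daugman's integro-differential operator and a compensated
    radial-gradient operator that down-weights isolated interference spikes
    (specular reflections, eyelashes, glasses), together with reflection
    inpainting and morphological eyelash suppression, a coarse pupil estimator
    or external bounding-box input in place of a learned detector, a synthetic
    eye-scene generator with exact ground truth, and an evaluation harness
    (IoU matching, precision/recall, circle-recovery benchmarks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
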
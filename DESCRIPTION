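Package: arnav
Title: Accuracy Evaluation of Augmented-Reality Surgical Navigation by
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the accuracy of augmented-reality (AR)
    navigation for laparoscopic liver surgery.  Implements hand-eye
    calibration of a tracked laparoscope from a stacked Kronecker-product
    linear system, point-based rigid image-to-patient registration by
    singular value decomposition, a rigid iterative-closest-point
    refinement for fiducial-model compensation, the AR transform chain
    from image space to camera pixels, and evaluation of target
    registration error (TRE) and fiducial localization error (FLE),
    including the marker-subset resampling experiment in which three to
    ten registration markers are drawn at random and the error is
    measured on the held-out marks.  A synthetic liver-phantom generator
    emulates pneumoperitoneum deformation, per-clinician annotation
    error, optically tracked tool sampling with breathing motion, and
    laparoscopic camera trajectories, so the complete pipeline can be
    exercised and validated without access to in-vivo data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
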
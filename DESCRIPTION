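Package: circumnut
Title: Stereo Reconstruction and Kinematic Analysis of Plant Circumnutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for quantifying circumnutation, the helical oscillatory
    movement of elongating plant organs, from calibrated two-camera time-lapse
    recordings. Reconstructs 3D landmark trajectories by lens undistortion and
    two-view triangulation, tracks landmarks across image stacks with pyramidal
    Lucas-Kanade optical flow and manual correction re-seeding, transforms
    trajectories into the plant reference frame, segments the movement into
    individual circumnutations at local maxima of the turning-angle signal, and
    computes per-circumnutation, whole-movement, point-wise and
    stimulus-relative kinematic features. Inter-operator reliability is
    assessed with per-frame trajectory distances, per-axis correlations and
    the two-way random-effects absolute-agreement intraclass correlation
    ICC(A,1). A fully parameterised simulator of circumnutating trajectories,
    stereo observations and rendered image stacks provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
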
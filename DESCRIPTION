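Package: headmotion
Title: Quantification of Rigid-Body Head Motion During MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying rigid-body head motion from pose streams
    recorded by markerless tracking devices during MRI examinations.
    Pose logs (time-stamped rotations and translations at ~30 Hz) are
    cross-calibrated into the scanner RAS frame, re-referenced to the
    temporal midpoint of a structural reference sequence, masked to the MR
    acquisition windows, and decomposed into translation and rotation
    components about the three anatomical axes.  Per-patient displacement
    metrics (mean, median, maximum displacement and motion-free time below
    a threshold) are computed for the tracked facial centroid and
    propagated to brain-region centroids, and cohorts (e.g. anaesthetised
    versus awake children) are compared with Mann-Whitney U tests under
    Benjamini-Hochberg false-discovery-rate control.  A synthetic motion
    generator with drift, nodding, spike and jitter processes provides
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
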
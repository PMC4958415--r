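Package: cupmig
Title: Marker-Based Migration of Acetabular Cups from Low-Dose 3D CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures three-dimensional migration of marker-equipped acetabular
    cups relative to the pelvis from low-dose CT volumes, in the style of
    radiostereometric analysis (RSA). Detects 1.0 mm tantalum fiducial beads
    with subvoxel precision, registers paired examinations on the pelvic
    rigid body by least-squares (SVD) fitting, and decomposes cup motion into
    three translations and three Cardan rotations. Includes a synthetic
    pelvic-phantom CT simulator with jig-controlled cup motions, a simplified
    stereoradiographic (RSA) gold-standard simulator with marker occlusion,
    and double-examination precision / gold-standard accuracy statistics
    with Student-t multipliers, plus RSA quality metrics (condition number,
    rigid-body mean error) and CT effective-dose estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
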
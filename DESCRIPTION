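Package: growcutvol
Title: GrowCut Segmentation and Volumetry for 3D Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automatic tumor volumetry from 3D scalar volumes (MRI) using the
    GrowCut competitive region-growing cellular automaton seeded from user scribbles,
    with region-of-interest restriction, precomputed similarity weights and saturated-
    voxel tracking for speed, plus a naive reference implementation as a correctness
    oracle. Includes binary morphological post-editing (dilation, erosion, island
    removal), Dice similarity and physical-volume evaluation with per-case and summary
    reporting, classical geometric volume models (spherical, ellipsoid, mean-radius,
    caliper) and bidimensional Macdonald measures, a synthetic contrast-enhancing
    ellipsoid phantom generator with ground truth and auto-generated scribbles, and
    NRRD/NIfTI volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
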
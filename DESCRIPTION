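Package: woundpatch
Title: Wound Area Measurement from Photographs Using a Fiducial Color Patch
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the physical area of skin wounds from single
    photographs that include a printed 3x3 color patch of known size
    (0.7 cm cells, 2.1 x 2.1 cm gross). The patch is detected
    automatically, a planar homography rectifies the scene to a
    fronto-parallel frame with a calibrated cm-per-pixel scale, the
    patch's reference colors drive an affine device/illumination
    normalization, and the wound boundary is segmented with a
    gradient-vector-flow (GVF) active contour initialized automatically
    by k-means clustering. Includes a pinhole-camera scene renderer for
    ground-truth validation studies over capture distance and angle,
    the conventional length-by-width clinical baseline, and
    longitudinal healing statistics (degree of decrease and the day of
    half the final decrement).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
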
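Package: swallowtrack
Title: Vision-Based Quantification of Cervical Skin Motion During Swallowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objectively quantifying neck-skin motion during
    swallowing from video of colored fiducial stickers. Provides a seeded
    synthetic session generator with ground truth, HSV-threshold marker
    detection and 3x3 grid labeling, pixel-to-millimeter calibration from
    the known sticker diameter, dropout-robust mean-trajectory excursion
    measurement (median over three guided swallows), and longitudinal
    two-arm trial statistics with baseline subtraction, outlier screening,
    t-tests and Mann-Whitney U subgroup comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
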
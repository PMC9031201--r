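Package: NestedContours
Title: Nested Iso-Contour Detection of Suspicious Lesions in Mammography Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects suspicious masses on 2-D grayscale mammography images with
    the nested contours algorithm (NCA): iso-intensity level sets are extracted
    over the whole brightness range at a constant gradation step, linked into
    nested chains, and chains whose successive contours stay geometrically
    similar are retained as lesion candidates. The package also provides the
    accompanying truncation-normalization/CLAHE three-channel pre-processing,
    annotation-consistent eightfold and mosaic training-set augmentation,
    detection evaluation (IoU matching, precision/recall, F1 and F-beta scores,
    11-point interpolated average precision, per-lesion-type tallies,
    two-proportion comparison), and a seeded synthetic phantom generator that
    emulates six mammographic lesion appearance types over four ACR breast
    density classes so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    mgcv,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
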
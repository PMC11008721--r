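Package: rownav
Title: Crop-Row Detection Geometry, Low-Light Enhancement and Navigation-Line Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for vision-guided inter-row navigation in row crops such
    as maize. Provides Retinex-based adaptive gamma correction for low-light
    field images driven by the weighted cumulative distribution of luminance
    levels; gap-aware weighted least-squares fitting of left and right crop-row
    lines from detected plant centres, with construction of the central
    navigation line; training-free reference implementations of common
    detection-network building blocks (efficient channel attention, coordinate
    attention, fast spatial pyramid pooling, space-to-depth slicing) and of the
    complete-IoU and composite detection losses; precision/recall/AP detection
    metrics and angular line-fit evaluation; and a synthetic field-scene
    generator with known ground truth, six-way photometric/geometric
    augmentation and mosaic compositing, so every stage is testable without a
    field dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
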
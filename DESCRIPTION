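Package: pumpkinpick
Title: Grasp and Cut Point Detection for Dome-Type Pumpkin Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for fruit and stem instance
    segmentations in trellis ("dome-type") pumpkin harvesting robotics.
    Matches each detected fruit mask to its stem mask using gravity and
    adjacency constraints, estimates the two grasping points and the
    cutting point from the fruit-stem centroid line geometry, refines
    coarse per-instance probability maps by iterative uncertain-point
    re-prediction (point rendering inference), and evaluates matching and
    segmentation quality with precision/recall and IoU-threshold average
    precision. Includes Labelme/COCO annotation readers and writers and a
    seeded synthetic-scene generator with exact ground truth so the whole
    pipeline is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
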
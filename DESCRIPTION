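Package: cobbangle
Title: Automated Cobb Angle Measurement from Vertebral Landmarks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated measurement of the Cobb angle in anterior-posterior
    spine radiographs of adolescent idiopathic scoliosis from vertebral
    corner landmarks (17 vertebrae, 4 corners each). Implements the
    landmark-geometry pipeline (detection-score filtering, x-center outlier
    rejection, curve-fit imputation of failed detections, gap-profile
    curvature quantification, apex and end-vertebra selection), local binary
    pattern features with an AdaBoost cascade for torso cropping of
    radiographs, keypoint-detector support math (focal loss, mean landmark
    error, center/corner offset-map decoding), a synthetic spine phantom
    generator with analytically known Cobb angle, and an observer-agreement
    evaluation suite (percentage accuracy, median/IQR summaries, intraclass
    and Pearson correlation, chi-square and Mann-Whitney tests) over a
    packaged 70-image measurement fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
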
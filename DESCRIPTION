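Package: kyphoscan
Title: Automated Thoracic Kyphosis Angle Measurement from Sagittal Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the thoracic kyphosis angle of a standing subject from
    a sagittal-view photograph or binary person mask. The pipeline segments
    the person silhouette, localizes the T1 and T12 vertebral levels by
    calibrated body-proportion ratios, extracts the dorsal back contour,
    measures the flexicurve chord length L and sagittal depth d, and
    converts them to an angle with the chord-sagitta arc formula
    theta = 2*asin(4dL/(4d^2+L^2)). Includes segmentation evaluation
    metrics (global/mean accuracy, mean/weighted IoU, boundary F1),
    method-agreement statistics (Spearman rho, intraclass correlation with
    confidence interval, Cronbach's alpha), and a synthetic silhouette
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
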
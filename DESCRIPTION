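Package: ebusemble
Title: Weighted-Ensemble Classification of Pulmonary Lesions in Radial EBUS Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pulmonary lesions as benign or malignant from
    radial-probe endobronchial ultrasound (EBUS) images. Implements the full
    three-model weighted soft-voting ensemble: a mutual-information-selected
    radiomics plus patient-data random forest, a whole-image convolutional
    classifier with a frozen backbone, and a patch-level convolutional network
    over 32x32 windows tiled in the 2-5 mm annulus around the probe, aggregated
    by a malignant-patch ratio threshold. Includes contrast stretching, ray-cast
    lesion boundary detection, 85 hand-computed radiomics texture and shape
    features (GLCM, GLDM, GLRLM, GLSZM, NGTDM, shape-2D, and an adaptive
    weighted-sum GLCM heterogeneity feature), class-asymmetric augmentation, and
    a seed-reproducible synthetic phantom generator so the whole pipeline runs
    and is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
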
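Package: leafclone
Title: Discrimination of Sugarcane Clones from Leaf RGB Images and NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether two sugarcane stalks growing close
    together in a densely planted (Simplified System) family trial are the
    same individual or distinct clones, from '+1' leaf samples. Stage one
    screens attribute scenarios (RGB band means, pretreated near-infrared
    spectra, and their combinations) by standardized pairwise Euclidean
    distance and ROC/AUC. Stage two is a pixel-resampling protocol that
    compares two leaf images through a Mahalanobis statistic D-squared,
    referred to a chi-squared distribution with one degree of freedom per
    attribute. Includes spectral pretreatments (Savitzky-Golay smoothing
    and derivatives, multiplicative scatter correction, mean centering),
    leaf segmentation from bright-background images, experimental-design
    pair enumeration and classification, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
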
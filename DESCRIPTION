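Package: usconf
Title: Confidence-Aware Evaluation of Skin Ultrasound Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anatomically grounded confidence assessment of
    high-frequency ultrasound (HFUS) skin image classifiers. Implements
    epidermis-mask-driven region-of-interest extraction, skin layer maps
    encoding per-pixel anatomical relevance, Grad-CAM saliency maps for a
    small built-in convolutional network, a classification confidence level
    (CCL) that scores the agreement between network saliency and relevant
    skin anatomy, and a multicriteria model-evaluation measure based on a
    percentile sweep over CCL values. Ships a seeded synthetic HFUS phantom
    generator (speckled four-class skin images with ground-truth epidermis
    masks and patient structure), Dice metrics and a generalized Dice loss,
    a trainable encoder-decoder epidermis segmenter, and a patient-wise
    cross-validated experiment pipeline with tidy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
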
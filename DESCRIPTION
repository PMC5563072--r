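Package: parquant
Title: Quantification of Cortical PAR Polarity in Zygote Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Image quantification for cell-polarity studies in the
    C. elegans zygote: extraction and straightening of membrane intensity
    profiles from midsection images, error-function boundary-model fitting
    for domain size and segregation efficiency, asymmetry and cluster
    indices, punctum detection with density-based asymmetry, kymograph
    cortical-flow speeds, photobleach-recovery curves, and a
    synthetic-embryo generator that supplies ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
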
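Package: nucshift
Title: High-Content Screening Analysis of NF-kB Nuclear Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based analysis pipeline for high-content screening of
    NF-kB (p65) nuclear translocation in adherent cell monolayers. Provides
    mask-based nuclear and cytoplasmic segmentation of two-channel
    fluorescence fields (nuclear stain plus reporter), per-cell NUC/CYT
    translocation scoring, 384-well plate quality control (Z-prime factor and
    coefficients of variation), single-point hit calling, four-parameter
    logistic dose-response fitting for EC50/IC50, and selectivity-index
    classification. A synthetic two-channel field and plate generator with
    known ground truth supports validation of every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
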
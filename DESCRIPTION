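Package: hetscreen
Title: Image-Based Screening Toolkit for Heterochromatin Regulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for high-content image-based RNAi screening of
    heterochromatin regulators and its companion assays. Provides nuclear
    segmentation and per-nucleus feature extraction from multi-channel
    fluorescence fields, Rank Product normalization with permutation p-values,
    three hit-calling schemes (intensity cutoffs, polynomial-kernel SVM,
    multi-metric distance rules with randomization-calibrated p-values),
    per-nucleus Pearson colocalization screening against a reference
    construct, position-effect-variegation eye-pigment quantification,
    IP-MS candidate enrichment filters, and seeded synthetic-data generators
    with known ground truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    EBImage,
    kernlab,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
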
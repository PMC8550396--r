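Package: orchidcolor
Title: Segmentation-Free Color Labeling of Orchid Flowers and Labella
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning color labels to orchid flower (CF) and
    labellum (CL) images without segmentation. Implements two color schemes
    over a 9 x 13 RGB reference matrix with a commutative primary/secondary
    color-combination algebra and exclusion lists; small convolutional
    classifiers with transfer-learning style layer freezing, replication
    oversampling and data augmentation; four label-fusion strategies
    (multi-class argmax, one-vs-rest logical merge with a domain-closure
    axiom, max-probability, and the MLTC/MLCR true-positive-rate ensembles);
    evaluation metrics including confusion matrices, macro-F1 and accuracy
    variants that include or exclude inconsistent predictions; and a seeded
    synthetic orchid-image generator so the whole pipeline is testable
    end-to-end without the real photographic dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
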
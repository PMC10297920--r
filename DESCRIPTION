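Package: ovimyo
Title: Muscle Fiber Morphometry and Breed-Comparison Transcriptomics for Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for studies of
    postnatal skeletal-muscle development in sheep breeds and their crosses.
    One track quantifies muscle histology: segmentation of boundary-stained
    (WGA-like) cross-sections, area and circularity filtering of candidate
    fibers, cross-sectional area (CSA) statistics, a hypertrophy fraction, and
    slow-twitch fiber typing from ATPase-like images. The other track analyses
    a gene-by-sample count matrix: median-of-ratios normalization, negative
    binomial Wald tests for differential expression, hypergeometric gene-set
    enrichment, a lightweight weighted co-expression module/eigengene/hub
    screen, fuzzy c-means expression-trend clustering, and a confidence
    interval classifier of crossbred expression bias toward either parental
    breed. A seeded synthetic-data generator provides ground truth for every
    stage, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    limma,
    mclust,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
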
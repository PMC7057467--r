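Package: dnbtip
Title: Dynamic Network Biomarker Analysis of Developmental Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tipping points (imminent critical transitions) in
    age-ordered gene-expression time courses using the dynamic network
    biomarker (DNB) composite index. Provides loading and rank-uniform
    normalization of expression matrices, age-based sliding windows,
    correlation-based dominant-group search, the composite index
    SDd * PCCd / PCCo with a leave-peak-out significance test and an
    optional permutation test, one-way ANOVA / Benjamini-Hochberg /
    fold-change differential-expression calling around the tipping point,
    exploratory ordination (hierarchical clustering, PCA, classical MDS),
    and a latent-factor simulator that plants a known critical transition
    with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
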
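Package: eosclust
Title: Fuzzy C-Means Phenotype Clustering for Early Onset Scoliosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated, per-etiology stratification of early onset scoliosis
    (EOS) patients by fuzzy C-means clustering of six pre-operative clinical
    indices (age, major curve Cobb angle, kyphosis, levels in the major
    curve, levels in kyphosis, and the deformity index, the ratio of Cobb
    angle to kyphosis). The number of clusters is chosen by maximizing the
    cohort-average maximum membership, low-membership subjects (< 0.6) are
    flagged as outliers, clusters are relabeled in ascending order of mean
    Cobb angle, and clusters are compared index-by-index with one-way ANOVA
    and Tukey HSD post-hoc tests. Includes a seeded truncated-Gaussian
    mixture generator for synthetic EOS cohorts, frozen-model scoring of new
    patients, and JSON/CSV export of every result.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
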
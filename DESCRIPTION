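Package: senoscreen
Title: Chemoinformatic Screening for Senolytic Candidates from Natural Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a descriptor- and
    fingerprint-based virtual screen for senolytic drug candidates in
    natural-product libraries. The pipeline selects a lead cluster of known
    senolytics from molecular descriptors (K-means, Ward, PCA), filters
    candidate libraries by the quantitative estimate of drug-likeness (QED),
    screens survivors against each lead by hashed path fingerprints and
    Tanimoto similarity with silhouette/Dunn cluster validation, and ranks the
    deduplicated hits by multitarget capacity on a compound-target-pathway
    network. A synthetic-data generator with planted analog families and a
    planted multitarget winner makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
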
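Package: chemotypr
Title: Metabolomic Chemotyping of Stress Responses from GC-MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for chemotyping plant stress responses
    from GC-MS metabolite abundance tables. Implements sample-median
    normalization, Dixon small-sample outlier exclusion, log transformation with
    autoscaling and group-aware k-nearest-neighbour imputation; PCA with group
    confidence ellipses; two-class OPLS-DA with variable importance in
    projection (VIP), cross-validated Q2Y, label-permutation testing and
    differential-metabolite selection; loading-ranked metabolite set enrichment
    analysis (MSEA) with a weighted running-sum statistic; and correlation
    network construction and comparison (Bray-Curtis on node degrees, Jaccard
    on edge sets, Ward clustering). Ships a synthetic-data generator that
    reproduces a two-genotype, two-oxygen-condition, three-timepoint factorial
    design with machine-readable ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
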
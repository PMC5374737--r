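Package: hocus
Title: Higher-Order Similarity Clustering for Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies patient cohorts from sparse binary or ordinal feature
    data (somatic mutations, thresholded copy-number calls, registered tumor
    voxel masks) by iteratively deriving higher-order sample-sample similarity
    metrics from a first-order Hamming similarity, clustering each metric with
    resampling-based consensus clustering (CDF/delta-area and silhouette model
    selection), selecting the metric order by centered kernel alignment with an
    outcome-derived co-survival similarity, and evaluating and characterizing
    the resulting subtypes with log-rank tests, Kaplan-Meier curves, and
    per-gene chi-squared association tables. Includes seeded generators for
    planted-community cohorts, coupled survival outcomes, and voxel phantoms so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
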
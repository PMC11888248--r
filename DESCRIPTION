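Package: atlasrep
Title: Cross-Atlas Cell-Cluster Replicability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the replicability of cell clusters across paired
    single-cell and single-nucleus transcriptomic atlases. Implements marker-gene
    specificity scoring (global one-vs-all and local best-vs-next AUROCs),
    Spearman-network neighbor voting with reciprocal best-hit detection and
    portable pretrained models, centroid-correlation cell calling for spatial
    transcriptomic panels with concordance statistics, coordinated-expression
    specificity across matched cluster centroids, and enrichment testing. Ships a
    seeded synthetic-atlas generator that plants ground-truth cluster
    correspondences, splits, and unique clusters so the full pipeline can be
    validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
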
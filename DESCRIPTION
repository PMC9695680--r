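Package: fieldagg
Title: Field-Level Aggregation of Pixel-Wise Crop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-image crop-type mapping workflows that classify
    multispectral satellite pixels and then collapse per-pixel class
    probabilities to one label per agricultural field. Implements spectral
    vegetation index feature generation (NDVI, two-band EVI, NDRE, MSAVI) and
    band normalization for Sentinel-2-style 13-band reflectance stacks,
    class-imbalance resampling (random over- and under-sampling, SMOTE) and
    class-weighted loss, and three pixel-to-field aggregation strategies:
    majority voting, probability averaging, and Bayesian log-odds evidence
    combination with optional probability smoothing toward the uniform
    distribution. A synthetic landscape generator (region-grown fields with
    class-dependent band signatures and a Dirichlet confusion model for
    per-pixel probabilities) supports end-to-end benchmarking without
    external data, and an evaluation harness reports overall accuracy and
    macro F1 at pixel and field level across resampling x classifier x
    aggregation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    EBImage,
    caret,
    optparse,
    ranger,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
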
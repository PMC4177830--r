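Package: airspace
Title: Alveolar Airspace Morphometry and COPD Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated quantification of alveolar airspace enlargement on
    haematoxylin-eosin lung histology and the accompanying clinical and
    molecular analyses used to link emphysema with aortic aneurysm.
    Images are pre-segmented by fuzzy c-means clustering with simultaneous
    multiplicative bias-field (luminance inhomogeneity) correction, refined
    by an exact graph-cut (Boykov-Kolmogorov max-flow) minimisation of a
    membership-driven Potts energy, split into connected airspace
    compartments, converted to physical units, and summarised by the D2
    moment-ratio diameter index with a minimum-diameter filter.
    Companion modules provide nonparametric group statistics
    (Mann-Whitney, Kruskal-Wallis, Kolmogorov-Smirnov with exact
    small-sample enumeration), GOLD spirometry classification with
    contingency and logistic odds-ratio cohort analysis including a
    propensity-score covariate, delta-Ct relative expression for qPCR
    triplicates, and seeded synthetic-data generators for histology
    images, vascular-surgery cohorts and qPCR panels so the whole
    pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
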
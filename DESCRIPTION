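Package: phagekit
Title: Quantitative Analysis of Bacteriophage Characterization Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bacteriophage characterization studies:
    titer estimation from decimal dilution-series plate counts with a weighted
    two-dilution estimator and limit-of-detection censoring, efficiency-of-plating
    (EOP) host-range grading and heatmaps, planktonic killing-assay metrics
    (OD600 area under the curve and virulence indices) with treatment-versus-
    control testing, and explant endpoint statistics (log10 transforms, Dunn's
    rank-based multiple comparisons, LDH binning with chi-square tests). A
    mechanistic phage-bacteria co-culture simulator generates every input the
    pipeline consumes, so the full analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
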
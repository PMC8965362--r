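Package: droughtgs
Title: Genomic Selection for Drought Response in Polycross Forest Tree Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end toolkit for quantitative-genetic analysis of drought
    response in replicated polycross progeny trials of forest trees. Includes a
    synthetic trial generator with known ground truth (polycross pedigrees,
    Mendelian SNP genotypes, multi-trait additive architectures, juvenile-trend
    basal area increment series and daily climate); the Canadian Fire Weather
    Index Drought Code with monthly anomaly scaling; tree-ring processing
    (basal area increment conversion, frequency-response spline detrending,
    dating quality checks, robust-mean chronologies, bootstrapped
    climate-growth correlations); Lloret resistance, recovery and resilience
    components of drought response; pedigree (A) and VanRaden genomic (G)
    relationship matrices; average-information REML fits of the individual-tree
    animal model with heritabilities, breeding values, theoretical accuracies
    and bivariate genetic and phenotypic correlations; family-stratified
    cross-validation of predictive ability; and multi-trait selection-index
    genetic gain scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
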
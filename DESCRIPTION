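Package: painsegr
Title: Brain System Segregation and the Progression of Chronic Pain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline linking resting-state brain network
    segregation to the longitudinal progression of chronic pain. From
    parcellated ROI time series and rigid-body motion traces it computes
    framewise-displacement motion QC, nuisance-cleaned Fisher-z functional
    connectivity, and per-network system segregation (W - B)/W; scores the
    Brief Pain Inventory and Pain Catastrophizing Scale into the composite
    pain-experience outcome; and runs the inferential chain of group
    comparisons, partial correlations, standardized-beta regressions with
    collinearity diagnostics, and moderation analysis with percentile
    bootstrap confidence intervals and Johnson-Neyman regions of
    significance. A synthetic cohort generator with block-covariance BOLD
    signals, autoregressive motion, and planted behavioral effects provides
    ground truth for parameter-recovery validation.
License: MIT
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
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
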
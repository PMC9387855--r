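Package: dynaflow
Title: Dynamic Activity Flow Modeling of Lagged Brain Network Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates dynamic, lagged, direct, and directional resting-state
    functional connectivity from multivariate neural time series via
    principal-component-regularized multivariate autoregression (MVAR), and
    uses those weights to predict future task activation dynamics in a target
    functional network ("dynamic activity flow modeling"). Includes
    time-resolved multivariate pattern decoding with subtrial averaging and
    balanced cross-validation, nonparametric group statistics,
    predicted-to-actual overlap scoring, connectivity-scrambling permutation
    nulls, lateralized motor ERP recovery, simulated network lesioning, and a
    ground-truth vector-autoregressive simulator for parameter-recovery and
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
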
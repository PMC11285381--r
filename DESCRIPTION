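Package: circacp
Title: Circadian-Guided Change-Point Detection of Sleep-Wake Cycles from
    Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of sleep and wake onset times from
    unlabelled wrist- or hip-worn actigraphy. A cosinor model locates the
    circadian cycle in each recording; within every cycle a single
    structural change point in the Gamma scale of the activity counts is
    found by minimising a modified information criterion, followed by a
    second-round refinement pass. Includes non-wear screening, a
    Calinski-Harabasz based error-detection step, marker-based validation
    statistics (Bland-Altman agreement, median absolute errors), and a
    zero-inflated Gamma simulator of actigraphy cohorts with known
    ground-truth onset times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
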
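Package: eegworkload
Title: EEG Band-Power Indicators and mRMR Channel Selection for Cognitive
    Workload Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting mental workload from
    multichannel EEG. Provides a synthetic multi-subject EEG generator with
    known ground truth, preprocessing (channel pruning, common-average
    re-referencing, zero-phase band-pass filtering, epoch segmentation),
    Welch band-power extraction, a 26-indicator spectral catalogue including
    gamma-band ratios, a minimum-redundancy-maximum-relevance (mRMR)
    indicator-evaluation statistic built on plug-in mutual information,
    greedy mRMR channel screening with cross-subject frequency aggregation,
    and few-channel classifiers evaluated with leave-one-subject-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
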
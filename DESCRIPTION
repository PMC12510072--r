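Package: szproject
Title: Personalised Seizure-Rate Projection and Drug-Effect Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses anti-seizure medication efficacy from chronic
    implanted-EEG event detections. Detects multidien (1-45 day) cycles in
    hourly interictal-discharge rates with a continuous Morlet wavelet
    transform and a permutation false-discovery-rate test, projects the
    long-term (90-day moving average) seizure rate 14 days ahead with
    rolling ARIMAX models using sine/cosine cycle phases as exogenous
    regressors, compares projection performance across drug-regimen
    segments (Kruskal-Wallis with Wilcoxon/Bonferroni post-hoc tests and a
    value-shuffled surrogate control), and monitors projection residuals
    against a +/- 3 standard-deviation reference band with
    persistence-based changepoint detection. Includes a virtual-participant
    simulator generating cyclically modulated seizure and discharge series
    with drug-effect changepoints, recording gaps and diary
    under-reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
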
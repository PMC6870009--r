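Package: gatenet
Title: Source-Space Functional Brain Networks from P50 Sensory-Gating ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of paired-click P50 sensory-gating
    experiments for three-group (first-episode schizophrenia, ultra-high-risk,
    healthy control) staging studies. Generates synthetic epoched EEG cohorts
    with a known forward model and planted cross-region coupling; preprocesses
    and averages epochs and scores P50 amplitudes, latencies and gating
    measures; computes a weighted minimum-norm (eLORETA-style) inverse and
    region-of-interest source time series; builds normalized mutual
    information connectivity matrices; derives graph metrics (characteristic
    path length, clustering coefficient, global efficiency); compares groups
    edge-wise by permutation tests with Kruskal-Wallis/Bonferroni statistics;
    and stages subjects with a post-pruned decision tree over demographic,
    cognitive, ERP and network features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    rpart,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
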
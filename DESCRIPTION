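Package: retex
Title: Returners and Explorers in Human Mobility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recurrence-aware human-mobility analysis built around the
    dichotomy between returners and explorers. Computes the total and
    k-radius of gyration and the s_k recurrence ratio from individual
    trajectories, classifies populations with the bisector rule or a
    Gaussian-mixture EM, fits truncated power laws to heavy-tailed radius
    and jump-length distributions, simulates trajectories with the
    exploration-and-preferential-return (EPR) model and its
    gravity-augmented d-EPR variant, derives global mobility networks and
    metapopulation invasion thresholds, tests mobility-class homophily in
    call graphs with a permutation null, and generates synthetic
    landscapes, archetype trajectories and call graphs so the full
    pipeline runs without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    igraph,
    jsonlite,
    pracma,
    tibble,
    yaml
Suggests:
    mclust,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
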
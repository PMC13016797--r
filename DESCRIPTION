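Package: kinpref
Title: Kin-Directed Mate and Social Preference Analysis for Dichotomous and
    Free-Swimming Choice Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify kin-directed sexual and social preference in
    small freshwater fish from dichotomous-choice and free-swimming group
    trials. Computes strength-of-preference (SOP) scores from association-zone
    occupancy, detects pairwise associations from multi-animal centroid
    trajectories via frame-wise Euclidean distance thresholds, aggregates
    observer-scored behavioural events into group-level count cells, and fits
    the full inference layer: linear and negative-binomial generalized linear
    mixed models with stepwise interaction pruning, likelihood-ratio analysis
    of deviance, Tukey post-hoc contrasts, Benjamini-Hochberg false discovery
    rate correction, rank-sum tests and cross-experiment Spearman consistency.
    Ships a synthetic-data generator (zone-occupancy Markov chains, socially
    biased correlated random walks in circular arenas, overdispersed behaviour
    counts) so the entire pipeline is testable without original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    dplyr,
    tidyr,
    readr,
    zoo,
    glmmTMB,
    car,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
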
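Package: labrepro
Title: Multi-Laboratory Reproducibility Assessment for Behavioral Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reproducibility of treatment effects
    across replicate experiments run in several laboratories. Provides
    per-replicate effect estimation with (generalized) linear mixed models,
    random-effects meta-analytic pooling across laboratories (REML or
    DerSimonian-Laird tau-squared), and classification of each replicate
    against the pooled result by three criteria: congruent significance
    (P_sig), coverage of the pooled effect by the replicate confidence
    interval (P_cov), and their conjunction (P_acc). Includes a synthetic
    multi-laboratory data generator emulating three insect behavioral
    experiment designs (two-group transformed-Gaussian responses, repeated
    binary choices with missingness, and per-dish binomial counts with
    overdispersion), so every pipeline stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
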
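Package: dreambench
Title: Assessment Toolkit for Reverse-Engineering Challenges in Systems Biology
Version: 0.1.0
Authors@R: person("dreambench", "developers", role = c("aut", "cre"),
    email = "dreambench@example.org")
Description: Scoring machinery for community reverse-engineering challenges in
    systems biology: exact enumeration scores for species-assignment tables,
    variance-normalized prediction error with column-resampling null models,
    Spearman rank-profile scoring of expression predictions, and ROC /
    precision-recall evaluation of ranked edge lists with analytic completion
    of truncated lists, empirical nulls and stretched-exponential tail
    extrapolation.  Also provides the null-mutant z-score network inference
    baseline, rank-sum consensus aggregation, community identifiability and
    systematic-false-positive analytics, and an in-silico gene-network
    simulator that emits data bundles in the challenge file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
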
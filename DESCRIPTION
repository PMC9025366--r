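Package: tritrend
Title: Three-Cohort Transcriptomic Trend Analysis for Aging and Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression, trend-crossing, enrichment and interactome
    analysis for a three-cohort (Young / Old / Old-with-AD) bulk RNA-seq design.
    Implements median-of-ratios normalization and a negative-binomial Wald test
    per two-cohort comparison, crosses the three DEG sets into Venn regions with
    trend-sign concordance labels (including the aging-down / AD-up "reversal"
    archetype), performs hypergeometric over-representation of gene sets on the
    shared DEG lists, and detects interactome hubs by betweenness-centrality
    z-score with cross-network intersection. A synthetic-data module generates
    cohort count matrices, gene-set collections and community-structured
    interactomes with known planted truth, so every stage is verifiable.
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
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
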
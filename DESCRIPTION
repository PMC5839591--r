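Package: randbias
Title: Random Gene-Set Survival Bias Analysis for Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the tendency of randomly chosen gene sets to
    stratify an expression cohort into groups with significantly different
    survival far more often than the nominal 5% ("random bias"). Scores
    samples by the first principal component of random gene subsets,
    median-splits, and compares log-rank p-values against an empirical
    null of random group assignments; tests the resulting proportion with
    a two-proportion Z statistic. Includes proliferation meta-gene
    residualization, half-split consistency analysis, shared-nearest-
    neighbor Louvain sub-classification, and a synthetic expression plus
    survival cohort simulator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
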
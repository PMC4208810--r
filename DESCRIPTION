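Package: icnx
Title: Integrative Copy-Number and Expression Clustering of Cancer Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative clustering of paired gene-level copy-number calls and
    expression profiles, as used to subtype cancer cell-line panels. Provides
    aberration burden and recurrence profiling from gain/loss/LOH call
    matrices, selection of putative driver genes whose copy-number state is
    concordant with their own expression (Mann-Whitney plus Spearman
    filters), resampling-based consensus clustering with Spearman distance
    and average linkage, significance analysis of microarrays (SAM) with
    permutation false-discovery q-values and nearest-centroid signature
    classification, single-sample gene-set enrichment (ssGSEA) scoring with
    rank normalization and subtype-specific pathway calls, differential
    IC50 drug-sensitivity testing between clusters, and a seeded synthetic
    cohort generator for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
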
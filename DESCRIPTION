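Package: mirdrift
Title: Age-Associated miRNA Promoter Methylation and Expression Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of age-associated microRNA regulation in
    tumor cohorts. Models per-miRNA expression trends with age using
    negative-binomial regression on raw counts, per-CpG methylation drift
    using linear regression on beta values, maps CpG probes to strand-aware
    promoter windows around miRNA transcription start sites, classifies
    miRNAs as concordant or discordant by the canonical epigenetic
    repression rule, scores and ranks candidates, validates directionality
    against an external cohort, and identifies convergently targeted hub
    genes in a bipartite miRNA-target network. Includes a synthetic
    multi-omics cohort generator with planted per-year effects for
    calibration and recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    limma,
    DESeq2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
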
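Package: sexbiasRV
Title: Sex-Stratified Expression Outliers and Sex-Biased Rare Variant
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects sex-stratified multi-tissue gene expression outliers,
    quantifies rare-variant enrichment in outliers via relative risks,
    scores rare variants with a hierarchical latent-variable model (EM over
    genomic annotations and binarized outlier signal), classifies sex-biased
    and sexually antagonistic functional rare variants against a sex-label
    permutation null, links them to gene-drug tables, and combines
    transcription-factor motif-disruption scores with variant posteriors
    into a sex-differential regulatory score. Includes an analytic
    two-normal mixture model of how sex stratification changes outlier
    discovery, and a synthetic-cohort generator (correlated multi-tissue
    expression with latent confounders, a rare-variant site-frequency
    spectrum, planted sex-scoped effects, and N2 carrier pairs) so the whole
    chain is testable without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
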
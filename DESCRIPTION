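Package: robustGEI
Title: Robust Mixed-Model Tests for Gene-Environment Interaction in Related Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-variant score tests for gene-environment interaction (GEI)
    and joint genetic/GEI effects in samples with related individuals or
    repeated measures. A linear mixed model is fitted once under the null by
    restricted maximum likelihood with arbitrary block-structured variance
    components; per-variant statistics then use a family-clustered Huber-White
    sandwich variance estimator, giving robust inference when environmental
    main effects are misspecified, at cost linear in sample size for bounded
    cluster sizes. Includes the individual-cluster, two-step residual and
    plain linear-model comparison strategies, a family-based simulation module
    (pedigrees, gene dropping, heritable exposures, calibrated trait models),
    and evaluation utilities (genomic inflation factor, empirical type I
    error, QQ data). Readers and writers cover PLINK1, VCF, pedigree tables
    and sparse kinship triplets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
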
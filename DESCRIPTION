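Package: rareburden
Title: Multi-Mask Rare-Variant Burden Meta-Analysis for Case-Control Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for gene-based rare-variant burden association
    studies of binary traits across multiple sequencing cohorts. Variants are
    pooled into up to 60 masks per gene from annotation criteria
    (protein-truncating and predicted-damaging missense classes) crossed with
    nested allele-frequency tiers. Per-study burden tests use Firth-penalized
    logistic regression with penalized-likelihood-ratio p-values and
    back-corrected standard errors; studies are combined by
    inverse-variance-weighted fixed-effects meta-analysis with Cochran
    heterogeneity statistics and a genotype-count-based saddlepoint adjustment
    of meta-analysis p-values under case-control imbalance. Mask p-values are
    collapsed to gene-level statistics with a layered Cauchy (ACAT)
    combination, with frequency- and annotation-restricted sensitivity
    re-combinations and quantile-based inflation diagnostics. Companion tools
    integrate results with common-variant association studies (exact-test
    enrichment grids, subset discovery, effect-size-versus-frequency power-law
    fits) and estimate liability-scale burden heritability by regressing
    squared standardized burden effects on gene burden scores. A synthetic
    multi-study cohort generator with a liability-threshold disease model
    makes the full pipeline testable without access to restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    knitr,
    rmarkdown
Config/testthat/edition: 3
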
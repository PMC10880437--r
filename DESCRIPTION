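Package: panelTMB
Title: Tumor Mutational Burden Estimation from Targeted-Panel Somatic VCFs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates tumor mutational burden (TMB) from annotated somatic
    VCF files produced by targeted capture panels. Implements a configurable
    variant-filter cascade (caller quality, intra-run recurrence, population
    germline databases, consequence-class policy, preservation-aware VAF and
    depth thresholds) with two built-in algorithm profiles, sample-level NGS
    quality gating, VAF-sweep plateau analysis, cohort summarization with
    TMB bins and top-decile selection, a biological-curation rule engine for
    TMB-high cases, and a seeded synthetic-cohort generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
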
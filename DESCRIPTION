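Package: paircall
Title: Paired-Sample Somatic SNV Calling and UV-Signature Annotation for
    Targeted-Amplicon Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Count-level variant designation for paired-tissue
    targeted-amplicon deep-sequencing experiments, built around the
    paired-lens design used to survey somatic coding variation in adult
    human lenses. Per-site allele-count (pileup) tables are turned into
    germ-line calls by a variant-allele-frequency threshold and into
    somatic calls by paired discordance between left and right samples,
    with depth and VAF retention filters and cross-pair recurrence
    exclusion. Calls are annotated with strand-aware HGVS c./p.
    consequences against a single-transcript gene model,
    transition/transversion class, di-pyrimidine context and UV-signature
    (pyrimidine-strand C>T) flags, and novelty against local variant
    catalogs. Cohort utilities compute panel allele frequencies, class
    tallies, shared positions between panels, and Fisher / chi-square
    contingency comparisons. A seeded simulator generates reference
    sequences, minus-strand transcript models, case-control genotype
    panels and paired pileups with injected germ-line and somatic
    variants plus truth sets for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
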
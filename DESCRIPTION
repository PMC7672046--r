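Package: varfunnel
Title: Case-Only Rare-Variant Prioritization for Adolescent Idiopathic
    Scoliosis Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for case-only rare-variant discovery in
    whole-exome cohorts of adolescent idiopathic scoliosis (AIS)
    patients: read-level genotype quality control, recurrence and
    reference-panel allele-frequency filtering, deleteriousness-predictor
    consensus, per-variant burden testing against reference panels
    (1000 Genomes CHS, ExAC EAS) by Fisher's exact and chi-squared tests
    with Benjamini-Hochberg false-discovery-rate control,
    novel/differential variant classification, hypergeometric gene-family
    enrichment, and genotype-phenotype subgroup association on clinical
    scoliosis features.  A synthetic cohort generator with planted,
    known-truth variants makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
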
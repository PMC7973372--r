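Package: mtier
Title: Multi-Tier Germline Variant Interpretation for Cancer Predisposition Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes germline (ClinVar, HGMD) and somatic (COSMIC, TCGA)
    database evidence into six clinical-significance classes for panel
    sequencing cohorts, computes allele-frequency enrichment of cohort
    variants against a reference population (gnomAD-style) with one-sided
    Fisher exact tests, summarizes variation at the gene, patient, and
    cohort level, assigns patients to provenance-defined genomic groups,
    and compares clinical outcomes (Kaplan-Meier, log-rank, Mann-Whitney,
    chi-square/Fisher) between groups. Includes a synthetic-data module
    that generates cohorts, database snapshots, and clinical outcomes with
    known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR,
    survival
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
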
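Package: leukdx
Title: Gene-Expression-Based Differential Diagnosis of Acute Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential diagnosis of BCR-ABL1-positive acute leukemia
    (B-lymphoblastic leukemia, acute myeloid leukemia, and mixed-phenotype
    acute leukemia) from bulk RNA-seq expression data. Implements
    lineage-signature gene selection from an FPKM matrix (fold-change, FDR
    and expression-level filters), per-gene positivity thresholds with AML
    and B-ALL scores and a two-score decision rule, a one-vs-one
    sigmoid-kernel support vector machine with leave-one-out
    cross-validation, reference-gene (ABL1) normalization for external
    cohorts, confusion-matrix and ANOVA score evaluation, DNA-vs-RNA variant
    allele frequency concordance, and a seeded synthetic expression
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
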
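Package: episignr
Title: DNA Methylation Episignature Discovery and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating DNA methylation
    episignatures from array-style beta-value matrices: empirical-Bayes
    moderated differential methylation on M-values, episignature probe
    selection, a linear support-vector classifier producing calibrated
    Methylation Variant Pathogenicity (MVP) scores with leave-one-out
    cross-validation, run-based differentially methylated region (DMR)
    calling, CpG-island and gene context annotation, cross-cohort
    differentially-methylated-probe overlap analysis, clinical-feature
    prevalence tables with explicit denominators, and a synthetic-cohort
    generator with planted signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
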
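Package: phenoscreen
Title: Phenotype-to-Transcriptome Screening for Mouse Models of Huntington's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links behavioural severity to transcriptional dysregulation in
    Huntington's disease mouse cohorts. Provides composite trait Z-scoring and
    extreme-performer ("good"/"poor") classification, rank-correlation screening
    of gene expression against behavioural traits with Benjamini-Hochberg
    control, qPCR delta-Ct relative quantification, a self-contained
    negative-binomial Wald differential-expression stage with median-of-ratios
    normalization, the four-way severity gene-set partition, and presence
    progression of severity gene sets among top-ranked differentially expressed
    genes across a CAG-repeat allelic series. A synthetic-cohort generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
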
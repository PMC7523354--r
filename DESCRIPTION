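Package: cernaweaver
Title: Competing Endogenous RNA Network Inference with CNV-Deficiency
    Survival Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    triple networks from differential expression, miRNA target-programme
    consensus voting, and Pearson coexpression filtering; scores hub
    lncRNAs by pair counts and extracts first-neighbour subnetworks;
    performs hypergeometric over-representation analysis against GMT gene
    sets; and screens copy-number deficiency (segment mean at or below
    -0.3 over gene exons) for prognostic value with univariate-then-
    multivariate Cox proportional hazards models. Ships a seeded
    synthetic-data generator that emulates multi-cohort miRNA arrays, an
    RNA-seq cohort with planted ceRNA triplets, programme-vote target
    tables, SEG copy-number files and survival outcomes, so every stage
    is testable against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
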
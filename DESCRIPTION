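Package: pgxstar
Title: Star-Allele Diplotyping and Metaboliser Phenotyping for CYP2D6 and CYP2C19
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns PharmVar-style star alleles and suballeles to phased
    pharmacogene haplotypes, combines them with structural-variant evidence
    (whole-gene deletion and duplication) into diplotypes, translates
    diplotypes into CYP2D6 activity scores and metaboliser phenotype classes
    (and categorical CYP2C19 phenotypes), and summarises cohorts as allele and
    phenotype frequency tables with chi-square comparisons against reference
    population frequencies. Ships curated allele-definition fixtures for
    CYP2D6 and CYP2C19, a Hardy-Weinberg synthetic-cohort generator with a
    ground-truth ledger, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
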
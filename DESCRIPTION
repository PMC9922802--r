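Package: mendelvar
Title: Variance Partitioning and Confounder Screening for Single-SNP
    Mendelian Randomization Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for nucleotide-level functional validation of a candidate
    SNP in panels of inbred-line F1 crosses. Implements the isofemale
    heritability estimator (the intraclass correlation t) that partitions
    trait variance into a component attributable to a biallelic locus under
    Hardy-Weinberg expectations and a pooled within-genotype component, with
    a one-way random-effects alternative; Weir-Cockerham SNP-wise F_ST and
    linkage-disequilibrium r2 screens of the genetic background of pooled
    cross panels; per-day fecundity, egg-volume, viability, development-time,
    starvation and dry-weight effect summaries; qPCR technical-replicate QC,
    geometric-mean reference normalization and GeNorm stability; and a
    synthetic F1-cross generator with known truth for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
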
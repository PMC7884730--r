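Package: hervscape
Title: hERV Expression Biomarkers, Absolute Immune Deconvolution and
    Genomic Feature Scoring for Colorectal Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving sequencing-based biomarkers in stage II/III
    colorectal cancer cohorts: quantification of human endogenous retrovirus
    (hERV) transcripts into the median.hERV statistic with noise-floor and
    expression filtering plus a downsampling robustness study; absolute
    immune-cell fraction deconvolution of bulk RNA-seq by nu-support-vector
    regression against purified-cell signatures on a common scale; a
    microsatellite-instability caller based on per-site read-length
    distribution shifts with paired-normal and baseline-panel modes; somatic
    variant filtering, tumor mutational burden, arm-level chromosomal
    instability, MATH intra-tumoral heterogeneity, a Lynch-syndrome
    classification rule and exact-binomial concordance statistics; and
    Kaplan-Meier/log-rank and Cox survival stratification by combined
    CD8/hERV and clinicopathological subgroups. A synthetic-cohort generator
    produces every input with the statistical structure the analyses assume,
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    survival,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
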
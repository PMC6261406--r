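Package: cnvcase
Title: Case-Control Copy Number Variation Analysis with Rare-CNV
    Filtering and Target-Specific Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide copy number variation (CNV)
    case-control studies in admixed cohorts: per-sample and
    per-chromosome CNV burden comparison with ancestry-adjusted
    logistic regression, construction of CNV regions (CNVRs) as unions
    of overlapping same-type calls, a four-step rare-CNV identification
    pipeline (control-cohort exclusion, population-frequency and
    known-variant panel filtering, dual-caller concordance), single and
    joint two-locus copy-number genotype association, and copy number
    quantification from qPCR triplicates (delta-delta-Ct) and droplet
    digital PCR (Poisson-corrected single-well estimates with 95%
    confidence intervals). Includes a synthetic admixed-cohort
    generator with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
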
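Package: lipidcourse
Title: Multi-Tissue Time-Course Lipidomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-tissue, sex- and time-resolved
    lipidomics studies: lipid shorthand nomenclature parsing and lipid-set
    construction, pooled-QC drift correction and quality filtering of
    untargeted feature tables, internal-standard semi-absolute
    quantification with class-level outlier handling and NIPALS imputation,
    empirical-Bayes moderated time-course contrasts, rank-based lipid-set
    enrichment and over-representation analysis, fuzzy c-means trajectory
    clustering, and cross-tissue correlation networks with signed-TOM
    co-expression modules. Includes a synthetic-study generator that
    emulates the endurance-training study design (9 compartments, 2 sexes,
    5 groups, n = 5) with planted effects and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    e1071,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
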
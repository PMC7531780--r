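Package: ClosedARM
Title: Closed Frequent Itemset and Class Association Rule Mining for
    Clinical and Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering association rules that jointly
    characterize comorbid chronic inflammatory conditions (type 2
    diabetes, dyslipidemia, periodontitis) from discretized clinical
    features and microarray gene expression. Implements closed frequent
    itemset enumeration with a brute-force oracle, association rule and
    class association rule induction with support, confidence,
    completeness and lift, guideline-based clinical discretization
    (including sex- and age-stratified waist/hip-ratio and abdominal
    circumference cutoffs), range-filter/z-score/ternary expression
    preprocessing, end-to-end analysis pipelines, and a synthetic cohort
    generator with planted patterns for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
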
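Package: methylrun
Title: Differential Methylation and Consecutive-Run DMR Analysis for
    Liver-Disease 450k-Style Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Infinium 450k-style DNA methylation
    beta-value matrices across multi-etiology liver-disease cohorts
    (normal liver, cirrhosis, hepatocellular carcinoma, cultured
    hepatocytes and HCC cell lines). Provides per-CpG two-group
    pooled-variance t-tests with Benjamini-Hochberg FDR and
    delta-beta thresholded call sets, detection of differentially
    methylated regions as maximal runs of consecutive consistently
    shifted probes, distribution of calls across CpG-island and genic
    features, metagene (tag-density) methylation profiles with
    expression-quartile stratification, stage-wise and
    primary-to-culture conservation analyses, Fisher's exact
    comparison of bisulfite clone tables, clinical cohort
    cross-tabulation, bedGraph/BED export, and a fully seeded
    synthetic cohort generator with planted effects for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
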
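Package: urometab
Title: Paired Urinary 1H NMR Metabolomics: Binning, Multivariate Models,
    AUC-Based Variable Selection and Pathway Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for paired-design urinary 1H NMR
    metabolomics. Simulates paired cohorts with planted biomarkers, aligns
    and adaptively bins frequency-domain spectra, normalizes to the total
    metabolome with log transform and pareto scaling, routes paired
    univariate tests through a Shapiro-Wilk normality check, fits PCA and
    OPLS-DA models with double cross-validation and permutation testing,
    ranks variables by AUC gain under random variable combinations (VIAVC)
    with best-subset selection, evaluates biomarker panels by ROC with
    bootstrap confidence intervals, screens clinical-score correlations
    with Bonferroni control, and performs hypergeometric
    over-representation plus relative-betweenness pathway topology
    analysis over a bundled pathway graph library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
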
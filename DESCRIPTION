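Package: ibdsubpheno
Title: Genotype-Subphenotype Association and Genetic Risk Scores for
    Inflammatory Bowel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the genetic architecture of clinical
    subphenotypes of Crohn's disease and ulcerative colitis under the
    Montreal classification. Provides an S4 cohort container built on
    SummarizedExperiment; per-variant association scans with linear,
    binary logistic, proportional-odds ordinal, multinomial and Weibull
    survival models conditioned on genotype principal components and
    correlated phenotypes; fixed-effect meta-analysis; genetic risk score
    construction from SNP and HLA dosages with cross-validated
    classification, continuum placement and score-outlier misdiagnosis
    detection; McKelvey-Zavoina variance decomposition and analytic power;
    Kaplan-Meier natural-history summaries; and a synthetic cohort
    generator with ground-truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    nnet,
    survival,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
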
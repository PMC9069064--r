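Package: microICT
Title: Gut Microbiome Markers of Immune Checkpoint Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal analysis of gut metagenomic profiles from cancer
    patients under anti-PD-1 immune checkpoint therapy. Provides a synthetic
    cohort generator emulating the structure of such studies (zero-inflated
    compositional species profiles, KEGG-orthology functional profiles,
    enterotype structure, BMI confounding, censored progression-free
    survival), alpha/beta diversity dynamics with a permutation spline test
    for longitudinal group comparison, BMI-adjusted per-species ANOVA with
    Tukey HSD contrasts and enrichment labelling, signed background-corrected
    reporter scores for pathway enrichment, Dirichlet-multinomial mixture
    enterotyping with model-order selection, Kaplan-Meier / log-rank survival
    stratification, and a two-tiered random-forest response classifier with
    repeated cross-validation feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
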
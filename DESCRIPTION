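Package: smokenet
Title: Smoking-Associated Biomarker Discovery with Implication Coexpression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies smoking-associated gene signatures from expression
    cohorts by inducing prediction-logic implication rules between pairs of
    mean-dichotomized genes, extracting group-specific differential network
    components, and selecting genes coexpressed with a panel of signaling
    hub genes. Includes network evaluation against gene-set and interaction
    annotations (network precision, q-value, permutation false discovery
    rate, subsampling stability), downstream prognostic modelling (Cox risk
    scores with a frozen 3-year ROC cutoff, Kaplan-Meier and log-rank
    stratification, multivariate Cox adjustment) and diagnostic validation
    (nearest-neighbour classification with odds ratios), together with a
    synthetic-cohort generator that plants known implication structure,
    survival effects and truth annotations for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
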
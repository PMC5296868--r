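Package: rescuepower
Title: Power Analysis for Preclinical Trials with Partial-Rescue Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based design of preclinical trials in slowly
    progressing disease models, built around cross-sectional natural-history
    data. Estimates per-group multivariate moments (means, variances,
    covariances) from wide cohort tables, simulates 2x2 factorial trials in
    which a hypothetical treatment rescues the mutant group mean toward
    wild type by a fraction r, and estimates Monte-Carlo power for single
    endpoints and for an elastic-net logistic composite endpoint. Also
    provides summary-statistics two-sample t-tests and standardized effect
    sizes for analyte panels with lower-limit-of-quantification censoring,
    and the omnibus/post-hoc decision tree (Anderson-Darling and Levene
    assumption checks, two-way ANOVA, Kruskal-Wallis with Dunn's test and
    Bonferroni correction, two-sample Kolmogorov-Smirnov) used for
    natural-history endpoint reporting. Ships a synthetic parameterization
    emulating a heterozygous Q111 knock-in mouse natural-history study so
    the whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    car,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
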
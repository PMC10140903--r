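Package: switchddm
Title: Diffusion-Model Decomposition of Task-Switching Costs and Latent
    Difference Score Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes task-switching costs in two-choice response time
    data into diffusion-model component processes (response caution,
    drift rate, non-decision time) via hierarchical Bayesian estimation
    with a contamination-mixture Wiener first-passage-time likelihood,
    and relates the components to visuospatial working memory capacity
    through latent difference score structural equation models.
    Includes a synthetic-data generator for task-switching and
    Recall-N-Back designs with user-specified latent population
    structure, conventional performance scoring (speed and probit
    transforms, repeated-measures ANOVA, partial-credit scoring and
    parceling), posterior predictive model comparison, convergence
    diagnostics, and end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
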
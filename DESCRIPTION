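Package: leafmn
Title: Leaf Manganese as a Proxy for Root Carboxylate Exudation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for site-structured ionomic surveys that use leaf manganese
    concentration as a field proxy for root carboxylate exudation. Resolves
    per-site positive and negative reference species (with cross-site average
    fallbacks), computes reference-normalised relative leaf Mn scores, and
    classifies target species with Welch t-tests against both references.
    Includes survey-level nutrient statistics (N:P phosphorus-limitation flags,
    heteroscedastic generalised least squares with AICc model selection and
    Tukey/Games-Howell post-hoc letters, PCA with KMO and Bartlett diagnostics,
    log-scale correlation matrices), phylogenetic comparative methods
    (Brownian-motion covariance, Blomberg's K with a randomisation test,
    maximum-likelihood ancestral states, PGLS, tip-rate correlations), and a
    synthetic-data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
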
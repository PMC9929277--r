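Package: solarbag
Title: Amortised Thermal-Lethality Scoring and Imbalance-Aware Learning
    for Solar Grain Disinfestation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing passive solar disinfestation of stored
    wheat against the rice weevil (Sitophilus oryzae). Implements a
    logarithmically amortising lethality score that labels above-threshold
    temperature episodes as effective or ineffective, a synthetic generator
    for diurnal weather and treatment-dependent bag-bottom temperatures,
    class-rebalancing transforms (random over- and under-sampling, SMOTE),
    entropy decision trees, bagged random forests and stagewise gradient
    boosting with stratified k-fold cross-validation, Shapley additive
    explanations for the fitted ensembles, and field thermal statistics
    (time above threshold, degree-minutes, Levene, one-way ANOVA with
    Tukey-Kramer compact letters).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
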
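Package: phyllosim
Title: Genomic Prediction Coupled with First-Year Tree Architecture Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples ridge-regression BLUP (RR-BLUP) genomic prediction of
    growth-model parameters with a first-year tree architecture simulator for
    an apple F1 bi-parental population. Primary growth is driven by thermal
    time (daily-mean or single-sine degree-days between base and upper
    thresholds), and sylleptic lateral emergence is a stochastic process whose
    daily probability is linear in the recent leaf-emergence rate. Includes
    estimators for the simulator parameters, balanced-design variance
    components and broad-sense heritability with exact F-based confidence
    intervals, genetic and phenotypic trait correlations, k-fold and
    leave-one-out cross-validation of genomic predictions, validation
    statistics (RMSE, nRMSE, bias), and a synthetic-data generator producing
    linked F1 marker matrices, polygenic trait architectures, replicated
    phenotypes at target heritabilities, and calibrated growing-season
    climate series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
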
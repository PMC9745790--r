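Package: nmixcam
Title: Binomial N-Mixture Models for Camera-Trap Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relative abundance of unmarked species from
    camera-trap count data with binomial N-mixture models (Poisson,
    negative-binomial and zero-inflated-Poisson abundance mixtures) and the
    Royle-Nichols occupancy-abundance model. Covers the full workflow: filtering
    photographs into independent events, pooling them into multi-day sampling
    occasions, aggregating cameras into site-level spatial replicates,
    covariate standardization and collinearity screening, maximum-likelihood
    fitting with covariates on abundance and detection, AIC model ranking,
    parametric-bootstrap goodness-of-fit with overdispersion (c-hat)
    correction, empirical-Bayes site-level abundance, and a synthetic-survey
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
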
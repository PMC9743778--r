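Package: prrda
Title: Permutation of Regressor Residuals Tests for Microbiome Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-abundance testing for microbiome count tables with
    the permutation-of-regressor-residuals (PRR) test applied to likelihood
    based count-regression models. The covariate of interest is replaced by
    its least-squares residual against the nuisance covariates and the
    residual rows are permuted to build the null distribution of the
    likelihood-ratio pivotal, which keeps the nominal false positive rate
    even under model misspecification. Supports eight families (Poisson,
    negative binomial, binomial, beta-binomial, each optionally
    zero-inflated) with library-size exposure, plus a simulation framework
    with known ground truth and false-positive-rate and power metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
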
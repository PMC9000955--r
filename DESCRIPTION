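Package: crmacro
Title: Consumer-Resource Models of Microbiota Macroecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coarse-grained consumer-resource dynamics of microbial
    communities under serial dilution with fluctuating resource supplies, and
    computes the macroecological statistics of the resulting relative-abundance
    time series (richness, Taylor's law variance-mean scaling, abundance-change
    distributions, restoring slopes, residence and return times, prevalence and
    rank-abundance curves, pairwise correlations). Consumption rates are drawn
    from a sparse random ensemble described by a handful of global parameters,
    which can be fit to longitudinal abundance tables by exhaustive grid search
    with susceptibility analysis. Includes comparison models: no-competition
    limits, saturation (Monod) kinetics, a metabolic trade-off variant,
    generalized Lotka-Volterra models converted from or moment-matched to the
    consumer-resource ensemble, and a non-interacting null model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
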
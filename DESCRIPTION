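Package: coralqg
Title: Quantitative Genetics of Coral Multi-Stressor Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for factorial multi-stressor experiments on
    clonally replicated corals: permutational MANOVA on multivariate phenotype
    profiles, per-trait linear mixed models with Tukey HSD post hoc tests,
    Bayesian broad-sense heritability via Gibbs-sampled variance partitioning,
    classification of combined-stressor responses against an additive null
    (synergistic, additive, antagonistic) with stratified bootstrap intervals,
    and genotype-mean correlation analyses to detect tradeoffs versus
    broad-spectrum stress resistance. Includes a synthetic-data generator that
    emulates a 12-genotype by 4-treatment tank experiment with known variance
    components, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    rjags,
    optparse,
    withr
Config/testthat/edition: 3
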
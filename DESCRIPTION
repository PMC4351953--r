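Package: gxebayes
Title: Frequentist and Bayesian Gene-Environment Interaction Analysis for a
    Candidate Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-track gene-by-environment association analysis of a
    single candidate polymorphism (5-HTTLPR, genotypes ss/sl/ll) against
    depression and anxiety phenotypes in a questionnaire cohort. The
    frequentist track fits additive-model logistic and linear regressions with
    sex and age covariates, genotype-by-stressor interaction terms, and
    permutation p-values (outcome permutation for main effects, residual
    permutation for interaction covariates), plus simulation-based power
    estimation. The Bayesian track performs model-averaged relevance analysis
    on discretized variables: Dirichlet-multinomial scoring of candidate
    parent sets, posterior probabilities of strong relevance, and full
    Bayesian odds-ratio posteriors within exposure and age subgroups. A
    synthetic-cohort generator with configurable effect sizes reproduces the
    marginal structure of the motivating study population so that every stage
    is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
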
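Package: adhereBayes
Title: Bayesian Prediction of Adolescent Adherence to Social Distancing
    from Pre-Pandemic Behavioural Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, fully simulatable inference pipeline relating
    adolescents' pre-pandemic social decision-making, behavioural and
    mental-health measures to their later self-reported adherence to
    COVID-19 social distancing. Provides deterministic scoring of
    behavioural tasks (dictator-game altruism, 27-item monetary-choice
    delay discounting, Cyberball rejection sensitivity, prosocial
    recoding and prorated questionnaire sums), exploratory factor
    reduction of questionnaire batteries (minres extraction, oblimin
    rotation, parallel analysis and Velicer's minimum average partial
    test), hierarchical Bayesian measurement models of a social-influence
    task with censored, heteroscedastic slider responses and correlated
    susceptibility slopes (via JAGS), Bayesian cumulative-probit ordinal
    regression of 5-category outcomes with multiplicity-adjusted highest
    density intervals and posterior effect-size classification, and a
    synthetic cohort generator that emulates the full study design so
    every stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
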
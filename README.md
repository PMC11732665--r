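# adhereBayes

Bayesian modelling of adolescents' adherence to COVID-19 social
distancing from pre-pandemic behavioural and mental-health measures.

## The problem

During the 2020 lockdowns, adolescents — for whom peer interaction is
developmentally central — varied widely in how closely they followed
social-distancing rules. A longitudinal design can ask which *pre-pandemic*
characteristics predicted later adherence: task-based prosociality and
susceptibility to peer influence, dictator-game altruism, delay
discounting, rejection sensitivity after simulated social exclusion, and
latent mental-health dimensions extracted from a large questionnaire
battery. `adhereBayes` implements that full inference pipeline for
researchers in behavioural epidemiology and developmental psychology, and
ships a synthetic cohort generator that emulates the whole study design so
every stage can be exercised and validated without access to restricted
cohort data.

## The models

**Outcome models.** Each 5-category ordinal outcome `Y` (self-rated
compliance; reverse-coded attendance at gatherings) is modelled by
cumulative-probit regression: a latent standard-normal variable
`Ỹ = b₁x₁ + … + bₚxₚ + ε`, `ε ~ N(0, 1)`, is partitioned by ordered
cutpoints `τ₁ < τ₂ < τ₃ < τ₄` so that
`P(Y ≤ k) = Φ(τₖ − Ỹ)`. With z-scored predictors the `b`'s read as
standardized coefficients. One model is fitted per predictor (plus four
covariates: age, assessment day, gender, intervention group), and because
11 predictors are tested, inference uses a multiplicity-adjusted
`1 − .05/11 ≈ 99.5%` highest-density interval alongside the 95% HDI,
plus posterior effect-size bin probabilities
(small `|b| ≤ .1`, small-to-medium, medium-to-large `|b| > .3`).
The sampler is a partially collapsed Gibbs/Metropolis scheme written in
the package (latent-response augmentation, conjugate coefficient draws,
collapsed random-walk updates of the cutpoints), cross-checked against
the frequentist probit MLE in the test suite.

**Influence-task measurement models** (fitted with JAGS via `rjags`).
Slider ratings in [0, 1] are treated as censored normal with point masses
at the endpoints. *Prosociality* is the participant random intercept of
the initial ratings, with scenario random intercepts and log-normal
person-specific residual SDs. *Susceptibility* regresses the second
rating on the initial rating and the decomposition
`delta = provided − initial`, `delta⁺ = max(delta, 0)`,
`delta⁻ = min(delta, 0)`, with correlated person-level random slopes on
`delta⁺`/`delta⁻`; a positive `delta⁻` slope means conformity toward less
prosocial peer ratings, i.e. susceptibility to anti-social influence.
Sensitivity families: ordered-beta (endpoint masses via two ordered
cutpoints, beta density inside) and Student-t robust regression.

**Scoring and reduction.** Prorated questionnaire sums (missing > 20% →
missing), dictator-game altruism, consistency-maximising discount-rate
scoring of the 27-item monetary choice questionnaire, Cyberball
rejection-sensitivity z-composites, averaging of the two pre-pandemic
time points (z-scored before and after), and factor reduction of the
30-scale battery by minres extraction with oblimin rotation, retained by
parallel analysis and Velicer's MAP test.

## Worked example

```r
library(adhereBayes)

cfg <- synth_config(n_participants = 300, seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> Synthetic cohort
#>   participants: 300 (T2: 266, T4: 134, outcomes: 131)
#>   influence trials: 9056 rows; questionnaires: 566 x 30
#>   seed: 7

scores <- score_predictors(cohort)          # altruism, discounting, rejection sensitivity
analysis <- merge(cohort$outcomes, scores, by = "participant_id")
fit <- fit_ordinal_model(analysis, outcome = "compliance",
                         predictor = "altruism",
                         settings = ordinal_mcmc(seed = 1))
fit
#> Cumulative-probit ordinal fit: compliance ~ altruism (+ 0 covariates)
#>   n = 130 (dropped 1); chains x iter = 4 x 1250
#>   altruism: mean 0.333, 95% HDI [0.145, 0.522], 99.5% HDI [0.076, 0.600]
#>   effect bins: small 0.01, small-medium 0.35, medium-large 0.64
#>   convergence: ok (max Rhat 1.010, min ESS 674)
```

The generating altruism effect in this cohort is 0.270 on the latent
standardized scale; the fit recovers a posterior mean of 0.33 with a 95%
HDI of [0.15, 0.52] at n = 130 — the coefficient means "about a third of
a latent standard deviation more compliance per SD of altruism", the
99.5% interval is the multiplicity-adjusted one used for decisions, and
the bin probabilities say the effect is very unlikely to be trivially
small. `run_pipeline(cfg)` runs the whole sequence — scoring, factor
reduction, the JAGS influence models, all 11 × 2 outcome models — and
returns the ranked results table plus a manifest with seeds, settings and
convergence diagnostics; `sensitivity_analysis()` refits the anti-social
influence predictor under the alternative response families. A thin CLI
(`inst/cli/adherebayes.R`) exposes `synth`, `all` and `sensitivity`
subcommands.

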
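# gxebayes

Two-track gene-by-environment association analysis for a single candidate
polymorphism — the serotonin-transporter promoter length variant 5-HTTLPR
(genotypes `ss`/`sl`/`ll`, `s` the low-expressing minor allele) — against
depression and anxiety phenotypes measured by questionnaire in a general
population cohort. The package is aimed at psychiatric-genetics and
genetic-epidemiology analysts who want the full pipeline — quality control,
population summary, regression model matrix, and Bayesian relevance
analysis — reproducible from a single seed, with a synthetic-cohort
generator standing in for subject-level data that cannot be shared.

## The two tracks

**Frequentist track.** Additive-model regressions code each subject by the
number of s alleles, g ∈ {0,1,2}, and fit

```
logit P(DEP = 1) = b0 + b_G g + b_sex sex + b_age age                (main effect)
logit P(DEP = 1) = b0 + b_G g + b_E e + b_GxE (g × e) + b_sex sex + b_age age
```

with e ∈ {0,1,2} the low/medium/high category of recent negative life
events (RLE; low = 0–1 events, medium = 2, high = 3+) or childhood
adversity (CHA; low = 0–3, medium = 4–6, high = 7+). Continuous outcomes
(Brief Symptom Inventory depression and anxiety scores, each the mean of
completed 0–4 items) use the same linear predictors under least squares.
The focal term (main effect or single-df interaction) is reported with
Wald statistic, normal-approximation CI, and a permutation p-value:
outcome permutation for main effects, and residual permutation of the
interaction column (the single-covariate GLM permutation scheme) for
interaction terms, `p = (1 + #{|t*| ≥ |t|}) / (n_perm + 1)`.
Simulation-based power estimation with bisection over n is included.

**Bayesian track.** Variables are discretized (genotype 3-level, exposures
and BSI bands 3-level, lifetime depression and age stratum 2-level) and
the dependency structure of each target is averaged exhaustively over all
parent sets of the declared candidate predictors, scored by the
Dirichlet-multinomial (Bayesian-Dirichlet) marginal likelihood with a
uniform equivalent-sample-size prior (`ess = 1` by default). This yields

- the posterior probability of strong relevance of a predictor — the
  model-averaged probability that it is a parent of the target(s);
- full Bayesian odds-ratio posteriors for a genotype level against the
  `ll` basis: each Monte-Carlo draw samples a structure, then parameters
  from their Dirichlet posteriors; structures without the genotype
  contribute an atom at OR = 1, so mixed posteriors are visibly bimodal;
- stratified grids of both quantities over RLE × CHA × age subgroups,
  including a combined multivariate phenotype (depression, BSI-depression
  and BSI-anxiety jointly).

## Worked example

```r
library(gxebayes)

# a cohort with the study's marginal structure and effect magnitudes
cohort <- generate_cohort(sim_config(n_subjects = 2358, seed = 42))

hwe_test(cohort)$p                       # genotype QC
#> [1] 0.8911624

fit_model(cohort, model_spec("DEP", "RLE", interaction = TRUE))
#>   term  estimate or_value         se      l95      u95     stat         p
#> 1  gxe 0.1600259 1.173541 0.08676223 0.990022 1.391079 1.844419 0.0651221
```

The fitted genotype-by-RLE interaction odds ratio is 1.17 per s allele
per exposure category, a trend at this sample size — effects of the
magnitude population studies report sit exactly at this detection
boundary, which is why the Bayesian subgroup view matters. With the
amplified signature configuration (a clearly detectable interaction and
anxiety main effect, see `?signature_sim_config`):

```r
sig <- generate_cohort(signature_sim_config(seed = 42))
stratified_relevance_grid(
  sig, or_spec = list(target = "dep", target_category = "yes",
                      reference_category = "no"), seed = 1)
#> Relevance grid: Pr(genotype strongly relevant for dep)
#>  rle_cat    n       pr prior_pr note or_median or_l95 or_u95 or_inclusion
#>      low 1706 0.000212    0.429 <NA>      1.00   1.00   1.00     0.000212
#>   medium  478 0.014906    0.429 <NA>      1.00   1.00   1.00     0.014906
#>     high  316 0.999229    0.429 <NA>      3.62   1.66   8.37     0.999229
```

Low-stress subjects show no support for a genotype effect on lifetime
depression (inclusion probability 0.0002, posterior collapsed onto
OR = 1), while in the high-stress stratum the genotype is a parent of
the outcome with probability 0.999 and an odds ratio of 3.6 (95%
credible interval 1.7–8.4) for ss versus ll — the model-averaging view
of a pure interaction. All numbers above are the output of the printed
calls at the stated seeds.

`run_study(analysis_config(...))` chains QC, summary table, the full
regression model matrix (three outcomes × four model families × three age
strata, permutation p-values for nominally significant cells), the
CHA-stratified interaction models and the Bayesian grids into one
seeded report.

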
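---
title: "Methods: two-track gene-environment analysis of 5-HTTLPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track gene-environment analysis of 5-HTTLPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gxebayes)
```

This vignette is the package's own account of its models, priors,
numerical choices and limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The scientific problem

5-HTTLPR is a repeat-length polymorphism in the serotonin-transporter
gene promoter; its short (s) allele lowers transporter expression and has
long been debated as a moderator of the depressogenic effect of life
stress. The analyses here ask three questions about a questionnaire
cohort genotyped at this single locus: (1) does the s allele show an
additive main effect on lifetime depression, current depressive symptoms
or current anxiety; (2) does the genetic effect on depression depend on
recent negative life events (RLE) or childhood adversity (CHA) — the
gene-by-environment (GxE) interaction; and (3) in which exposure/age
subgroups is the genotype *relevant* in the Bayesian model-averaging
sense, and with what effect size.

## Cohort data model

One row per subject: site label, sex, age in years (18–60), genotype
(`ss`/`sl`/`ll`), RLE count, CHA score, lifetime-depression indicator and
two Brief Symptom Inventory (BSI) scores on the 0–4 scale, each the sum
of completed item scores divided by the number completed so that partial
response still yields a score. Derived variables are pure functions of
the raw fields with fixed boundaries, boundary values always falling in
the upper band:

* BSI bands: low `[0,1)`, moderate `[1,2)`, severe `[2,4]`;
* RLE: low 0–1, medium 2, high ≥3; CHA: low 0–3, medium 4–6, high ≥7;
* age strata: young ≤30, old >30 (30 itself is young);
* additive genotype code: number of s alleles, ll=0, sl=1, ss=2.

Missingness is propagated, never imputed; every analysis is complete-case
on exactly the variables it uses, so effective Ns differ across models.
Genotype QC is the 1-df asymptotic chi-square against Hardy-Weinberg
proportions at the observed allele frequency — adequate at these counts,
so no exact test is provided — and the site-pooling check is a logistic
regression of site membership on the additive code.

## Frequentist track

Lifetime depression is modelled by maximum-likelihood logistic
regression, the BSI scores by least squares. Sex (0 = male, 1 = female)
and age (years, uncentred) are covariates in every model. Grouped
exposures enter ordinally (0/1/2) and the GxE interaction is the single
degree of freedom `g × e`; dummy coding of the exposure is available
(`env_coding = "dummy"`) but not the default, because grouped and
continuous codings behave near-identically for these data shapes and a
single-df interaction keeps one odds ratio per model cell. Focal terms
are tested by Wald statistics (matching the reporting convention of
standard genetic-association toolchains), with CI = estimate ± 1.96·SE,
exponentiated for logistic models. Nominal two-tailed 0.05 is the
significance threshold; no multiplicity correction is applied by default
(the analysis is a replication design), but `run_study()` annotates a
Bonferroni threshold for a user-declared test count.

Permutation p-values use the add-one correction
`(1 + #exceedances)/(n_perm + 1)`:

* **Main effects** permute the outcome across subjects, keeping all
  covariates attached to subjects.
* **Interactions** cannot be tested that way (outcome permutation also
  destroys the main effects), so the residual-permutation scheme for a
  single GLM covariate is used: the interaction column is regressed on
  all other design columns, its residuals are permuted and substituted as
  the tested covariate, and the refitted Wald statistics are compared.

Nonconvergence or separation yields a flagged result (`converged =
FALSE` with a note), never a silent omission. Logistic fits use a
convergence epsilon of 1e-12 so that estimates and standard errors agree
with an independently coded IRLS to well below 1e-6 (verified in the
tests on random small datasets).

Power is estimated by Monte Carlo: the fraction of simulated cohorts
whose focal asymptotic p falls below alpha, with a Clopper-Pearson CI,
and `required_sample_size()` bisects the noisy power curve for the
smallest n reaching a target.

## Bayesian track

All variables are discretized as above. The structure space is the set of
parent sets of the declared target(s), drawn from a fixed candidate list
(genotype, sex, age stratum by default, plus exposures where
appropriate), enumerated exhaustively up to `max_parents` (default 4,
every candidate of the largest conditioning set used here; at most 12
candidates are allowed). When predictors are exogenous and targets are
sinks — the case throughout — parent-set membership coincides with
Markov-blanket membership, so "posterior probability of strong relevance"
equals the summed posterior weight of models containing the predictor.
This deliberately restricts the full DAG-averaging methodology to the
sub-space that matters for relevance-of-predictors questions; exhaustive
enumeration then replaces MCMC exactly.

Each parent set is scored by the Dirichlet-multinomial marginal
likelihood with uniform equivalent-sample-size prior: with q parent
configurations and r target categories, `alpha_jk = ess/(q·r)`. The
default `ess = 1` follows the standard BDeu convention; it is
deliberately conservative — a 3×3 association that is nominally
significant at p ≈ 1e-4 can still favour the empty model at n ≈ 500 —
and is configurable. The structure prior is uniform over admissible sets;
`prior_inclusion_probability()` gives the baseline against which
posteriors should be read (0.43 for 3 candidates with `max_parents = 2`).

The Bayesian odds ratio of genotype level `x` versus the `ll` basis for a
target contrast (depression yes/no; BSI severe vs low, the moderate band
retained in fitting but marginalized out of the contrast) is sampled by
mixture: draw a structure from the model posterior; if the genotype is
not a parent, the draw is exactly 1; otherwise draw the target's
conditional probability tables from their Dirichlet posteriors and
average over the non-genotype parent configurations weighted by their
empirical frequencies before forming the odds ratio. The posterior
therefore contains an atom at 1 with mass `1 − Pr(inclusion)` next to a
continuous component — the bimodality is informative, and the reported
`atom_mass` and `inclusion_prob` quantify it. Defaults: 10 000 draws
(4000 in the pipeline, a runtime choice), central 95% credible interval,
density outline on the log-OR scale with fixed bandwidth 0.05.

Subgroup analyses rerun the whole discretize–enumerate–sample chain
independently per stratum (RLE × CHA × age, with level merging such as
CHA medium+high supported); empty or undersized strata are reported as
missing cells. The combined multivariate phenotype (lifetime depression,
BSI-depression band, BSI-anxiety band) is implemented two ways, because
the construction is genuinely underdetermined: the default enumerates the
three targets jointly (the posterior factorizes) and reports the
probability that the genotype is a parent of *at least one* target;
alternatively `discretize_cohort(composite = TRUE)` builds a two-level
composite variable (affected = lifetime depression or either BSI band
severe). The union reading is the default because it preserves each
phenotype's own dependency structure.

## The synthetic-cohort generator

`sim_config()` defaults encode the study conditions the analyses are
meant to face: n = 2358 subjects, s-allele frequency 0.427 with genotypes
drawn in Hardy-Weinberg proportions, 69% female, ages 18–60 drawn from a
Beta(1.1, 2.1) shape (mean ≈ 32.5 years, ≈47% aged ≤30), RLE categories
67/19/14% with mean count ≈1.21, CHA categories 65/18/17% with mean
score ≈3.29, and 41% lifetime-depression prevalence. Within-category
count distributions for RLE and CHA are a free design choice (only the
category proportions and means are externally constrained) and were fixed
once to match those means. Depression risk follows a logistic model in
the additive genotype code, ordinal RLE category and their product;
effect-size defaults are at the magnitudes the motivating study reported
(interaction OR ≈ 1.2 per allele per category, genotype main effect on
anxiety ≈ 0.054 score units per allele). The two BSI scores are censored
correlated normals (correlation 0.6, residual SD 0.9 score units) shifted
by their own linear predictors, and the mean-centred latent anxiety feeds
the depression logit (`beta_anx_dep`, default 0.7 per score unit), giving
mediation analyses a real channel to detect.

What the generator does *not* emulate: item-level BSI factor structure,
site effects beyond a label, questionnaire nonresponse patterns, and the
right skew of real symptom scores — a censored normal matched to the
reported mean (≈0.85) and SD (≈0.97) yields band proportions of roughly
63/29/8% rather than the reported 68/18/14%. Passing tests therefore
demonstrate correctness of the machinery under a faithful but idealized
data-generating process, not distributional realism of symptom scales.

Two derived configurations matter for validation:

* **Recovery/calibration configs** set `beta_anx_dep = 0`. With the
  comorbidity channel active, the latent anxiety term is an unmodelled
  covariate and logistic non-collapsibility attenuates the *marginal*
  interaction coefficient by a few percent relative to the injected
  conditional one; switching the channel off makes the injected
  coefficient exactly the estimand of the fitted model, which is what a
  recovery check should target.
* **`signature_sim_config()`** encodes the qualitative pattern of
  interest — pure GxE on depression, direct genotype effect on anxiety,
  weak anxiety→depression coupling — with magnitudes (0.35, 0.45, 0.15
  and 0.3 respectively) sized by pilot power calculations so that a
  *single* cohort of 2500 displays the pattern reliably under the
  conservative `ess = 1` score. The pattern metric is the posterior mean
  of the OR draws, which reflects both the atom at 1 and the shifted
  mode; the paper-magnitude defaults sit at the detection boundary by
  design and would make a single-run qualitative check a coin flip.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed; child streams are
  derived from the root seed and a stage label, global RNG state is saved
  and restored, and equal configurations give byte-identical output.
* Log-domain arithmetic throughout the Bayesian track (lgamma sums,
  log-sum-exp normalization); posterior weights sum to 1 within 1e-12.
* Percentages in the summary table are rounded half-up to integers,
  matching the reporting style of population-description tables.
* Permutation p-values use the add-one correction and so are never zero;
  the smallest reportable value is `1/(n_perm + 1)`.
* Degenerate inputs: constant focal columns and empty outcome classes
  are validation errors; empty strata are missing cells; an empty
  reference category in the OR contrast flags the result as degenerate
  rather than failing (the Dirichlet prior keeps it finite).

## Problem sizes in the test suite

The suite validates calibration with 500 null cohorts of n = 2300 at 200
permutations each, interaction recovery with 200 replicates at n = 2300,
Bayesian interval coverage over 100 simulated strata of n = 800, and the
signature pattern on one cohort of n = 2500 — sizes chosen to keep the
Monte-Carlo error of each check a few times smaller than the effect being
verified while the whole suite stays in the minutes range.

## Known limitations

* Single candidate polymorphism, additive coding only; no dominance or
  recessive models, no multi-locus machinery or LD handling.
* The Bayesian track averages over parent sets, not unrestricted DAGs;
  relevance probabilities are not comparable numerically to
  implementations that average over Markov-blanket graphs with different
  priors, and no causal identification is attempted.
* Posterior probabilities reported by the original study's
  relevance-analysis software arose from real data and an unpublished
  prior/model configuration; this package reproduces the *method class*
  and its qualitative behaviour, not those numbers.
* With `ess = 1` the BD score is conservative for multi-level parents at
  moderate n; users comparing against likelihood-ratio tests should
  expect relevance posteriors to lag nominal significance.
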
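---
title: "Recalibrating rare-disease risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating rare-disease risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case-control studies are often the only practical way to assemble enough
cases of a rare disease to estimate covariate effects, but the risk
probabilities such models emit are calibrated to the enriched sampling
fraction, not to the population a screening programme cares about. The
motivating system is Maturity-Onset Diabetes of the Young (MODY), a rare
monogenic diabetes that must be discriminated from insulin-treated type 1
diabetes: an enriched case-control sample (about 40% cases) trains a
clinical-features model, while a population-representative cohort (about
0.6% prevalence) anchors its calibration. The population cohort also
carries C-peptide and islet-autoantibody results, which are decisive —
C-peptide negativity or antibody positivity argues strongly against MODY —
but were collected under a screening cascade, so the gold-standard genetic
test (and hence the outcome label) is observed only for the
C-peptide-positive, antibody-negative subset.

`raremix` implements, on a common data contract, the recalibration routes
one can take through this situation, and the hierarchical mixture model
that combines them with the biomarker information.

## Models

All risk models share the logistic linear predictor over five clinical
features: parental diabetes, age at recruitment, HbA1c (%), age at
diagnosis and sex (baseline male). Coefficient priors are vague normal
(mean 0, sd 10) throughout.

1. **Training model** (`fit_training_model`): Bayesian logistic regression
   in the case-control data; records the training disease odds
   (cases/controls).
2. **Conversion table** (`build_conversion_table`, `apply_conversion`):
   the original development's approach. A threshold at each probability
   band's lower edge defines a hypothetical test; its sensitivity and
   specificity on the training data give a positive likelihood ratio, and
   post-test probability = LR+ x target prior odds. Consequences the
   package reproduces: outputs are grouped (piecewise constant), never
   fall below the target prevalence, and depend on the banding chosen.
3. **Offset updating** (`albert_offset_predict`): shifts the training
   linear predictor by log(target odds) - log(training odds). Valid when
   the covariate-specific likelihood ratio is the same in both
   populations; the shift is monotone, so the AUROC is exactly the
   training model's.
4. **Re-estimation** (`fit_reestimation`): refits the model directly in
   the population cohort, ignoring the training data. Unbiased but very
   uncertain at rare-disease prevalences.
5. **Joint recalibration** (`fit_joint_recalibration`): the shrinkage
   model logit(p) = gamma0 + gamma1 * z, where z is the case-control
   linear predictor for a population subject. Fitted *jointly*: each MCMC
   draw of the case-control coefficients recomputes every z, so training
   uncertainty propagates into gamma. gamma0 = 0, gamma1 = 1 means no
   recalibration is needed; priors are normal(0, 10) and normal(1, 10)
   respectively, centred on that null. A `method = "plugin"` variant fixes
   z at its posterior mean and demonstrably understates gamma uncertainty.
6. **Mixture model** (`fit_mixture`): splits population subjects on the
   composite indicator T (1 if C-peptide negative or antibody positive).
   T = 1 subjects share one disease probability with an informative
   Beta(2.2, 7361.3) prior (mean about 3e-4), taken as given from external
   evidence; T = 0 subjects follow a re-estimation or joint-recalibration
   branch. A logistic membership model for T on BMI, age at diagnosis, age
   at recruitment (restricted cubic splines, 3 knots) and parental
   diabetes lets `predict_mixture` marginalise over missing biomarker
   status draw-wise: p = q * p1 + (1 - q) * p0. `testing_utility_report`
   exposes the two conditional predictions and q so the value of ordering
   a biomarker test is explicit.

### Scenario semantics

- **a** — analyse the whole population cohort, explicitly imputing
  screened-out (unlabeled) subjects as disease-negative. This is logged as
  a modelling assumption each time it is applied; it is defensible here
  because the screening biomarkers essentially rule the disease out, and
  would not be in settings without that clinical argument.
- **b** — restrict to the biomarker-screened (T = 0) subset.
- **c** — mixture models only: all subjects, with biomarker composition in
  the model. Validation for b/c uses the T = 0 subset, the only subjects
  with gold-standard labels.

## The synthetic-data generator

The real datasets are access-restricted, so `generator_config()` +
`generate_population()` / `generate_case_control()` emulate their
structure from a single generating logistic model:

- Defaults encode the study conditions: 177/278 case-control composition,
  a population of 1,171 at 0.6% prevalence, and biomarker conditionals
  (P(C+|case) = 0.99, P(C+|control) = 0.20, P(A+|case) = 0.01,
  P(A+|control) = 0.60) chosen once so the realized composition
  approximates the emulated cohort's 924 C- / 151 C+A+ / 96 C+A- split.
- Generating coefficients default to the published clinical-features point
  estimates (3.22, -0.09, -0.68, 0.10, 1.35). The intercept is tuned by
  bisection so the expected prevalence over the sampled covariates matches
  the target within 1e-4 — prevalence is treated as a known population
  quantity, not a free parameter.
- Covariate families are stand-ins (the source reports only that the two
  cohorts were "broadly similar"): diagnosis age from a truncated normal
  on [1, 35], a gamma-distributed diagnosis-to-recruitment gap (so
  recruitment age never precedes diagnosis age), lognormal BMI, HbA1c
  truncated normal on (4, 16), Bernoulli sex and parental history. All are
  config-overridable.
- The case-control sample is drawn from a large latent population by
  outcome-dependent sampling. Because selection acts on the outcome alone,
  the covariate-specific likelihood ratio is preserved between designs *by
  construction* — the offset method's assumption holds exactly, and
  `covariate_shift_variant()` is the only way to break it (scaling a
  population coefficient or changing a covariate distribution).
- One integer seed expands deterministically into per-stage substreams;
  identical configurations are byte-identical.

What the generator does **not** emulate: biomarker statuses depend only on
disease status (conditionally independent given the label), so on
synthetic data the T-membership model discriminates weakly (AUROC near
0.59, versus 0.76 reported on the real cohort, where biomarker status
co-varies with clinical features among non-cases). Passing tests therefore
validate the machinery and the constraints, not real-data discrimination
of the membership model. There is also no family structure, no treatment
history, and no continuous biomarker scale.

## Computation

Posterior sampling is a block-structured kernel (Rcpp): adaptive
random-walk Metropolis over all regression-type parameters jointly
(Haario-style covariance adaptation with Robbins-Monro scale tuning during
burn-in, frozen afterwards), with the constrained branch probability —
posterior-independent of the other blocks — updated by univariate slice
sampling on the logit scale. Chains start from a GLM (Laplace)
approximation fitted per block, whose covariance also seeds the proposal;
blocks where the GLM fails (separation, one-class outcomes) fall back to a
neutral start with a small isotropic proposal. Continuous covariates are
standardised internally and coefficients reported on the natural scale;
the shrinkage parameters are unaffected because z is invariant to that
reparametrisation.

Numerical choices: Bernoulli log-likelihoods use the stable softplus form
(no overflow for any finite linear predictor); `inv_logit` clips at |x| =
700 and returns values strictly inside (0, 1); split R-hat is floored at 1
and defined as 1 (with a degeneracy flag) when all chains are constant;
convergence failures warn but never error, matching the practice of
retaining occasional poorly-mixed bootstrap refits rather than silently
dropping them (they are flagged when they contain fewer than 3 cases).

Default chain settings are 4 chains of 20,000 iterations (10,000 burn-in);
`mcmc_config(full_scale = TRUE)` restores the production-scale 500,000 /
300,000 configuration. These are simple generalised-linear posteriors that
converge quickly, so the package's replicate-heavy experiments use
explicitly smaller configurations, chosen once as the package's problem
sizes:

- no-shift gamma-recovery replicates (20 fits at population n = 20,000):
  2 chains x 15,000 / 7,500;
- the assumption-violation sweep (200 simulated datasets at n = 2,000,
  prevalence 0.05): 2 x 3,000 / 1,500 per fit;
- bootstrap stability (B = 100 per mixture variant on the 1,171-subject
  cohort): 2 x 4,000 / 2,000 per refit;
- conjugacy checks: 2 x 30,000 thinned by 5, giving 10,000 near-independent
  draws of the one-dimensional branch parameter.

## Design choices that were genuinely open

- **Knot placement** for the restricted cubic splines: 10th/50th/90th
  percentiles of each covariate in the fitting data (standard for 3 knots;
  the source does not state placement).
- **Prior scale location**: the vague normal(0, 10) priors are applied on
  the internally standardised coefficient scale; at sd = 10 the data
  dominate either way and reported coefficients are natural-scale.
- **T-model population**: fitted to all population subjects regardless of
  disease status — the membership model has no disease conditioning in its
  likelihood, and this reading keeps it estimable from every subject.
- **Unlabeled T = 1 subjects** enter the constrained branch with their
  label treated as observed-negative; the count of such imputations is
  reported by the fit and the assumption is logged whenever applied.
- **Conversion-table inputs** are posterior-mean point probabilities
  (matching the original frequentist construction); a per-draw variant is
  possible through the same interface but is not the default.
- **Band-edge conventions** follow the published table exactly: the first
  band is open at both ends, later bands include their lower edge, the
  last band includes 1.
- **Validation populations**: scenario a validates on all subjects with
  unlabeled set to negative; scenarios b and c validate on the tested
  (T = 0) subset — the only subjects with gold-standard outcomes.

## Known limitations

- Biomarkers are binary; continuous titres are out of scope.
- The generator's biomarker model limits what synthetic experiments can
  say about membership-model discrimination (above).
- The no-recalibration recovery experiment requires the population to be
  generated at the case-control case fraction (177/455); at rare-disease
  prevalence the shrinkage intercept correctly absorbs the enrichment
  offset instead of returning 0 — that is the method working, not failing,
  but it means gamma0 = 0 is only the right target under matched designs.
- Conversion-table outputs inherit the documented grouping and
  prevalence-floor artifacts; they are reproduced deliberately.
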
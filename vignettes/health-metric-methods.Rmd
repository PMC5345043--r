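---
title: "Constructing a common longitudinal health metric: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a common longitudinal health metric: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(healthtrait)
```

## The problem

Longitudinal ageing studies measure health with dozens of heterogeneous
ordinal items — self-reported difficulties with daily activities,
sensory ratings, banded walking-speed and cognitive tests — and the item
set changes from wave to wave. Comparing a person's (or a population's)
health across waves therefore requires a single latent metric that (a)
is justified by the dimensional structure of the items, (b) links waves
through the items they share, and (c) tolerates item-parameter drift in
the items that change. `healthtrait` implements that workflow end to
end, together with the validation analyses a study team would run on
the resulting score, and a synthetic-cohort generator with retained
ground truth so that every stage can be tested for parameter recovery.

## Stage 1: unidimensionality screening

All items are first recoded so that higher categories mean worse health
(`recode_direction`), measured tests are banded into ordinal groups
(`band_percentile` for timed tests using the 25th/75th percentiles,
`band_sd` for scored tests using one standard deviation around the
mean, `recode_orientation` for the four-question orientation test), and
persons missing at least 25% of the baseline items are excluded
(`filter_participants_fa`; the quoted rule is inclusive, so exactly 25%
missing excludes). Banding statistics are computed on the banded wave
only, not pooled across waves; band boundaries close into the medium
band. These are deterministic rules, and all filters are idempotent.

The screen itself is a two-stage factor analysis on a stratified 70/30
development/validation split (`split_sample`):

* **Polychoric correlations** (`polychoric_matrix`): two-step
  estimation — thresholds from inverse-normal cumulative marginals,
  then the latent correlation by maximising the bivariate-normal
  rectangle likelihood of each pairwise-complete contingency table. The
  bivariate normal CDF is evaluated with Sheppard's single-integral
  form and 64-point Gauss–Legendre quadrature (absolute error below
  1e-10 over the clamped search range [-0.999, 0.999]). Indefinite
  pairwise matrices are smoothed to the nearest positive-semidefinite
  correlation matrix by eigenvalue truncation, with a flag.
* **Factor count** by Velicer's minimum average partial test
  (`map_test`): for m = 0, 1, ... partial out the first m principal
  components and average the squared off-diagonal partial correlations;
  the minimising m wins. An identity-like matrix yields zero factors.
* **Extraction and rotation**: minimum-residual (OLS) extraction
  (`efa_minres`) followed by geomin oblique rotation
  (`rotate_geomin`), minimising $\sum_i \big(\prod_j (\lambda_{ij}^2 +
  \varepsilon)\big)^{1/m}$ with $\varepsilon = 0.01$ by gradient
  projection with ten seeded random starts (the best criterion value is
  kept; the identity start is always included, and a single factor is
  returned unrotated).
* **Assignment and confirmation**: items join every factor on which
  their absolute rotated loading is at least 0.25 (ties included;
  `assign_items`), and the resulting structure is confirmed on the
  validation sample by a second-order confirmatory model
  (`cfa_second_order`): items load on their first-order factors, which
  are connected only through a general factor, $\Phi_1 = \gamma\gamma'
  + \mathrm{diag}(1-\gamma^2)$. Estimation minimises the unweighted
  least-squares discrepancy; the $\chi^2$ is $(N-1)$ times the
  ML-form discrepancy evaluated at the ULS solution, and CFI, TLI and
  RMSEA (with a noncentral-$\chi^2$ 90% interval) are computed against
  the independence baseline (`fit_indices`).

A full-information ML treatment of missing ordinal data would require
high-dimensional integration; given the 25% baseline missingness cap,
pairwise-complete polychoric estimation keeps the bias small and the
computation tractable, and is the package's deliberate choice. The same
applies to ULS versus weighted least squares with a full asymptotic
weight matrix: the indices are comparable in behaviour, not in exact
value, to those of heavier estimators.

## Stage 2: the Bayesian multilevel graded ogive model

The measurement model for item $i$, person $p$, wave $w$ is the graded
normal-ogive

$$P(X_{pwi} \ge k \mid \theta_{pw}) = \Phi(a_{iw}\,\theta_{pw} - b_{iwk}),$$

with ability decomposed into a wave effect and a person-wave residual:

$$\theta_{pw} = u_w + e_{pw},\qquad u_w \sim N(0, \sigma_u^2),\qquad
e_{pw} \sim N(0, \sigma_\theta^2).$$

$\theta$ is coded as *ill-health* (aligned with the item coding); the
reversal to "higher is better" happens only in the 0–100 transform.
Persons deliberately have no random effect inside the measurement
model: longitudinal dependence between a person's waves is handled
downstream by the mixed model, keeping the two stages separable.

Four variance configurations control how item parameters vary across
waves:

| id | wave structure |
|----|----------------|
| M1 | none: $a_{iw}=a_i$, $b_{iwk}=b_{ik}$ |
| M2 | threshold offsets $d_{iw}\sim N(0,\sigma_{b,i}^2)$, item-wise variance |
| M3 | as M2 with one shared variance $\sigma_b^2$ |
| M4 | M2 plus wave slopes $a_{iw}\sim N(a_i,\sigma_{a,i}^2)$ and hyperpriors $a_i\sim N(\mu_a,\tau_a^2)$, $b_{ik}\sim N(\mu_b,\tau_b^2)$ with estimated hyperparameters |

Anchor items (administered in every wave) carry the common scale;
wave-varying items simply contribute no observations where they are not
administered, and their parameters in the remaining waves are shrunk
through the wave-level distributions. Missing cells are skipped under a
missing-at-random assumption; person-waves with more than half of the
administered items missing are excluded beforehand
(`filter_personwave_irt`; "more than half" is strict, so exactly half
is retained).

**Sampler.** The probit link admits exact conjugate data augmentation: a
latent $Z_{pwi}\sim N(a_{iw}\theta_{pw} - d_{iw}, 1)$ truncated between
the thresholds of the observed category, followed by conjugate normal
updates for abilities, wave effects, slopes and offsets, inverse-gamma
updates for all variances, and a random-walk Metropolis step for the
ordered category thresholds. The threshold step is taken against the
ogive likelihood with the augmented data integrated out (they are
redrawn immediately afterwards — a partially collapsed update), which
mixes far better than the uniform conditional given $Z$; its proposal
SDs are tuned during burn-in toward 20–50% acceptance. Truncated
normals are drawn by tail-aware inverse-CDF inversion, accurate in both
tails. A logistic-link model would forgo all of this conjugacy, which
is why the probit was chosen.

**Identification.** After every sweep the scale is fixed by dividing all
slopes by their mean and multiplying abilities, wave effects and the
two ability SDs accordingly (thresholds and offsets are untouched);
the likelihood is invariant under this rescaling and the mean posterior
slope equals 1 to machine precision. Priors are weakly informative and
overridable: $a_i \sim N(1, 2)$ truncated positive, $b_{ik} \sim
N(0, 4)$ ordered, all variances $\mathrm{IG}(1, 1)$, M4 hyper-means
$N(0, 10)$.

**Chain settings.** The default chain is 5,000 iterations with 100
burn-in. A burn-in of 100 is short for a model of this size, so the
fitted object is screened with a Geweke diagnostic on the variance
chains; on failure the first half of the retained draws is discarded as
additional burn-in, with a warning. The deviance used by the DIC is
evaluated on every fifth retained draw by default (`dev_every`) — the
DIC is an average, and thinning its evaluation changes nothing
statistically while saving a third of the runtime.

**Outputs.** EAP scores are posterior means with posterior SDs
(`eap_scores`); EAP reliability is
$\mathrm{Var}(\hat\theta)/(\mathrm{Var}(\hat\theta)+\overline{\mathrm{psd}^2})$;
the DIC uses $p_D = \bar D - D(\hat\vartheta)$; the wave-level ICC is
the posterior median (with central 95% interval) of
$\sigma_u^2/(\sigma_u^2+\sigma_\theta^2)$ — the ability-variance
definition, recorded here because a score-variance decomposition would
be an equally defensible reading. Model comparison ranks by EAP
reliability and breaks ties toward the lower DIC; because the
reliability is itself a Monte-Carlo estimate, differences below
`rel_tol = 0.02` (about its MC noise at these chain lengths) count as
ties, and genuine disagreement between the criteria is flagged rather
than silently resolved. The 0–100 transform maps the pooled ability
range linearly onto [0, 100] with a sign reversal (worst observed
ability scores 0, best 100); its parameters are stored, and
out-of-range abilities under a stored transform clamp with a warning.

## Stage 3: validation analyses

* `fit_lmm`: the health score on covariates with crossed (not nested)
  random intercepts for persons and waves, fitted by maximum likelihood
  through `lme4` — ML rather than REML so that the likelihood-ratio
  test against the ordinary linear model (`lrt_vs_linear`, naive
  $\chi^2_2$ reference, conservative at the variance boundary) and the
  AIC ($-2\ell + 2(k_{\mathrm{fixed}}+3)$) are coherent.
* `mcfadden_adjusted`: $1 - (\ell_{\mathrm{full}} -
  k_{\mathrm{full}})/\ell_{\mathrm{null}}$; `conditional_icc`:
  $(\sigma_\alpha^2+\sigma_\gamma^2)/(\sigma_\alpha^2+\sigma_\gamma^2+\sigma_\varepsilon^2)$.
* `auc_empirical`: Mann–Whitney AUC with ties counted one half and a
  DeLong placement-value interval, oriented so that a *lower* health
  score predicts the adverse outcome. "Adjusting by gender" is
  operationalised as stratification: the adjusted AUC is the
  case–control-pair-weighted average of within-gender AUCs with a
  stratified DeLong variance (`auc_gender_adjusted`) — a deliberate
  reading, since covariate-adjusted ROC has no single canonical
  definition. `compare_auc` is the paired DeLong test on the same
  subjects (the chronic-condition count entering negated for
  orientation), stratum-weighted the same way.
* `chronic_count` sums the eight condition flags, treating missing
  flags as absent with a reported count.

## Stage 4: pattern mining

The score is binned into four classes at 20/40/60 (right-closed:
a score of exactly 20 is class 1). The classifier stack is built on a
single primitive: a decision tree over categorical covariates with
binary level-set splits chosen by information gain in bits
(`grow_tree`), stopping at `max_depth`, `min_leaf` (default 20, so
extracted rules keep meaningful support) or zero gain, with leaf ties
broken toward the lowest class. Note one consequence of the zero-gain
stop: a perfectly balanced XOR-type configuration has zero root gain
for every split and yields a single leaf — greedy gain splitting only
solves such problems when the cell counts are unbalanced.
`bagged_forest` adds bootstrap rows and per-split feature subsets
(`mtry` defaulting to $\lceil\sqrt p\rceil$) with out-of-bag
predictions; `mda_importance` reports permutation importance in
accuracy points (×100); `cv_accuracy` is stratified k-fold;
`extract_patterns` grows 100 seeded trees on bootstrap samples with
per-tree feature subsets, reads every root-to-leaf path as a
conjunctive rule, scores its confidence on the full sample (a config
switch allows OOB-only evaluation; full-sample is the default and the
recorded choice) and keeps rules with accuracy ≥ 0.40 — against the
0.25 accuracy of a random four-class classifier. `top_patterns` keeps
the five most accurate rules per class (ties: larger support, then
fewer conditions) and counts factor occurrences over the selected set.

## The synthetic cohort

`generate_cohort` draws, under one seed: an item catalog (45 items of
2–5 categories, round-robin factor assignment over 5 first-order
factors, 8 cross-loading items, 39 anchor / 6 wave-varying items);
ten person-level covariates with simple independent marginals (gender,
age group, wealth quintile, education, physical activity, smoking,
drinking, falls, social network, employment — realism of the joint
distribution is deliberately *not* attempted, recovery tests need known
structure); latent ill-health $\theta_{pw} = u_w + \sum_c \gamma_c
x_{pc} + e_{pw}$; graded-ogive responses with wave drift in thresholds
(SD 0.3) and slopes (SD 0.1) after the anchor wave; MCAR missingness at
5%; and probit-linked outcomes (ten-year mortality at base rate 20%,
institutionalisation at 2%, eight chronic conditions) driven by
baseline ill-health, with the mortality slope solved numerically so
that the latent trait's AUC for mortality is 0.73 and 0.72 for
institutionalisation — discrimination levels typical of broad health
metrics in ageing cohorts.

Two generator choices deserve comment.

* **Factor structure.** Items of one first-order factor share a
  person-level residual (`factor_resid_sd`, default 0.5; cross-loading
  items pick up their secondary factor at half weight) on top of the
  general trait, so a factor screen on the default cohort finds five
  correlated first-order factors under a general factor. Setting
  `factor_resid_sd = 0` reduces the generator exactly to the fitted
  unidimensional measurement model, which is what the IRT
  parameter-recovery runs use: recovery must be judged against data
  from the fitted class.
* **Variance defaults.** $\sigma_u = \sigma_\theta = 0.7$ puts the
  wave-level ICC at 0.5, the middle of the plausible range for a
  slowly drifting population health level. The magnitude of cross-wave
  item-parameter drift is not an empirically calibrated value — real
  studies rarely report it — so the defaults (0.3/0.1) are free
  parameters chosen to be large enough that drift-aware models
  measurably beat the anchor-only model, and they are stated, not
  hidden.

What the generator does **not** emulate: realistic covariate joint
distributions, informative (non-MCAR) missingness, survey weights, or
mortality feedback on later-wave participation. Tests passing on this
cohort therefore demonstrate correctness of the estimators under their
own assumptions, not robustness to the selection processes of a real
panel study.

## Problem sizes used by the test suite

The validation suite runs parameter recovery at 20 items × 6 waves ×
1,000 persons with 3,000-iteration chains (five seeded replicates),
model comparison at 15 items × 300 persons with 800-iteration chains
(ten replicates), the factor-screen recoveries at n = 2,000–5,000, and
the cohort-level qualitative checks at the default 500-person cohort
with shortened chains — sizes chosen so the full suite completes on a
single CPU in about ten minutes while leaving each check enough
resolution to fail visibly when the code is wrong. The acceptance
script runs the four-model pipeline at the default cohort size with
1,500-iteration chains, and performs the baseline factor screen on a
dedicated 3,000-person cohort: the polychoric likelihood works on
contingency tables, so a well-powered screen costs little more than an
underpowered one, whereas a 45-item screen on a 350-person development
sample is simply too noisy to resolve five factors (Velicer's test is
conservative at small n). Chain length is a fitting choice, not a
generator condition: the paper-default 5,000/100 remains the package
default for real analyses.

One honest wrinkle of the default cohort deserves note: its
confirmatory fit indices are attenuated (CFI high-0.8s rather than
high-0.9s) relative to what clean second-order data would give, because
discrete covariates make the latent trait a normal mixture (polychoric
estimation assumes latent normality) and because assignment errors from
the EFA propagate into the confirmed structure. Refitting with the
generating assignment recovers adequate fit (the acceptance script
reports both), and the second-order estimator itself is verified
exactly on population matrices in the unit suite.

## Known limitations

* Pairwise polychoric + ULS is not an exact substitute for
  full-information categorical estimators; fit indices are comparable
  in behaviour, not value.
* The wave ICC is defined on ability variance; a score-variance reading
  would differ.
* The LRT against the linear model uses the naive boundary reference
  (conservative).
* DIC for latent-variable models is sensitive to the focus of
  inference; here the deviance conditions on $\theta$, the standard
  choice for this sampler family.
* The crossed mixed model treats wave effects as crossed with persons;
  with monotone attrition a nested reading could be argued.
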
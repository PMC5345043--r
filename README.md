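# healthtrait

Builds a single 0–100 health metric from heterogeneous ordinal health
items collected across the waves of a longitudinal ageing study, and
validates it. The package is aimed at biostatisticians and
epidemiologists working with panel studies whose health batteries —
ADL/IADL difficulties, sensory ratings, banded walking-speed and
cognitive tests — change from wave to wave, so that naive sum scores
are not comparable over time.

## The model

After a unidimensionality screen (polychoric correlations, Velicer's
MAP test for the number of factors, minres EFA with geomin oblique
rotation, and a second-order CFA with CFI/TLI/RMSEA), the metric is
built from a **Bayesian multilevel graded normal-ogive IRT model**:

```
P(X_pwi >= k | theta_pw) = Phi(a_iw * theta_pw - b_iwk)
theta_pw = u_w + e_pw,   u_w ~ N(0, sigma_u^2),   e_pw ~ N(0, sigma_theta^2)
```

for item *i*, person *p*, wave *w*. Anchor items (asked in every wave)
carry the common scale; items that vary across waves get wave-level
item-parameter distributions (threshold offsets `d_iw`, and in the full
model wave-specific slopes with hierarchical item priors). Estimation
is Gibbs sampling with truncated-normal data augmentation and a
Metropolis step for the ordered thresholds; identification fixes the
mean item slope at one after every sweep. EAP ability estimates are
transformed to a 0–100 scale (higher = better health). Model variants
are compared by EAP reliability and DIC.

Downstream, the package fits a crossed random-intercept mixed model of
the score on social determinants, computes the adjusted McFadden
pseudo-R² and conditional ICC, compares the score against a
chronic-condition count for predicting ten-year mortality with
gender-stratified DeLong AUCs, and mines decision-tree pattern rules
(information-gain trees, bagged forests with permutation importance,
40%-confidence rule filter, top five rules per health class).

A seeded synthetic-cohort generator (`generate_cohort`) reproduces the
full statistical structure the analysis assumes — 45 ordinal items on
five correlated first-order factors under a general factor, six waves,
39 anchor + 6 wave-varying items, MCAR missingness, covariate-driven
latent health, probit-linked mortality/institutionalisation and chronic
conditions — with ground truth retained for recovery testing.

## Worked example

```r
library(healthtrait)

cfg <- pipeline_config(
  generator = generator_config(n_persons = 500, seed = 42),
  irt_models = c("M1_none", "M4_hierarchical_full"),
  n_iter = 1500, burn_in = 200, seed = 42)
res <- run_pipeline(cfg, out_dir = "artifacts")

res$factor$map$n_factors      # factors suggested by the MAP test
res$irt$comparison$table      # EAP reliability and DIC per model
res$irt$icc                   # wave-level ICC of ability
res$irt$sum_r                 # |r| between metric and mean sum score
res$determinants$icc          # conditional ICC of the mixed model
res$determinants$auc_health   # gender-adjusted AUC, score vs mortality
res$determinants$auc_chronic  # same for the chronic-condition count
head(res$patterns$mda, 3)     # permutation importance of covariates
```

On this seed the run prints:

```
> res$factor$map$n_factors
[1] 5
> res$irt$comparison$table
                 model eap_reliability    DIC   pD
1              M1_none          0.9505 193175 2937
2 M4_hierarchical_full          0.9325 188436 1997
> res$irt$comparison$selected
[1] "M4_hierarchical_full"
> res$irt$icc
$icc
[1] 0.662
$ci
[1] 0.457 0.870
> res$irt$sum_r
[1] 0.964
> res$determinants$icc
[1] 0.498
> res$determinants$auc_health
AUC = 0.726 [95% CI 0.664, 0.788] (gender_adjusted)
> res$determinants$auc_chronic
AUC = 0.596 [95% CI 0.521, 0.672] (gender_adjusted)
> head(res$patterns$mda, 3)
     feature  mda
1   activity 5.76
4 employment 1.02
2  age_group 0.94
```

Reading the numbers: the MAP test recovers the five generated
first-order factors; the hierarchical model (M4) is selected — its DIC
is clearly lower, and its EAP reliability is within the Monte-Carlo
equivalence band of the anchor-only model's (reliability differences
below 0.02 count as ties, broken by DIC; see the methods vignette); the
wave-level ICC estimates the share of ability variance attributable to
waves (the generator's truth is 0.5, and the 95% interval covers it);
the metric correlates at 0.96 with the naive mean sum score while
remaining wave-linkable; the mixed model attributes about half the
score variance to its random effects; and the health score clearly
outperforms the chronic-condition count at predicting the generated
ten-year mortality (AUC 0.73 vs 0.60), with physical activity — the
strongest generated determinant — ranked first by permutation
importance. This is the qualitative fingerprint the pipeline is
designed to reproduce.

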
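---
title: "Methods: trait-methylation modelling and mortality-risk transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-methylation modelling and mortality-risk transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`methspan` connects three layers of an aging study in socially stressed
mice — longitudinal healthspan traits, liver CpG methylation, and survival —
through two complementary models and a cross-model synthesis. This vignette
explains the models, their assumptions, the tunable parameters, the
synthetic-data generator used to validate everything offline, and the
numerical choices made where the design was genuinely open.

## Study structure the package assumes

Two cohorts of male mice (C57BL/6J, CD1, Sv129Ev) experience lifelong
chronic psychosocial stress and are phenotyped on a shared schedule of eight
timepoints (weeks 12 and 16, then months 6–16 every two months;
`timepoint_grid()`). Cohort A (46 animals) is phenotyped to month 16 and
sacrificed at month 17 for a liver methylation array (beta values in [0,1]);
cohort B (345 animals) is followed to natural death. Strain is encoded
across two booleans ("C57BL/6J or Sv129Ev", "CD1 or C57BL/6J") to avoid
imposing a linear order on three strains, and social rank ordinally
(0 subordinate, 1 undefined, 2 dominant); `encode_covariates()` pins these
encodings and rejects unknown labels.

## Model 1: pseudoinverse trait-methylation regression

The beta matrix is modelled as `M = T C` with `C = pinv(T) M`, where `T` is
the trait matrix standardized by dividing each trait by its sample SD
(deliberately not centered — a bias column of ones carries the offset) and
`pinv` is the thin-SVD Moore–Penrose pseudoinverse with the standard
`max(dim) * eps * max(singular value)` cutoff. Traits are predicted back
from methylation through `T_pred = M pinv(C)`; the bias row of `C` yields a
constant pseudo-trait prediction that is computed and discarded.

Three filters surround the fit:

* **Collinearity mask** (`collinearity_filter()`, threshold 0.7). Traits are
  sorted by timepoint descending (ties by name; rank and strain, which have
  no timepoint, last), the symmetric Spearman matrix is formed, entries on
  and above the diagonal are masked *except* those in the rank/strain
  columns, the rank/strain rows are masked entirely, and any trait whose row
  retains a correlation above 0.7 is dropped. The asymmetric masking means
  that of two redundant traits the later-timepoint one survives, and that a
  trait correlated with rank or strain is removed rather than the covariate.
  The comparison is on the raw signed correlation, as specified; an
  `use_abs` switch offers the more common absolute-value reading.
* **Site predictability** (`loo_site_quality()`, threshold 0.5). For each
  animal a model is fitted on the remaining animals and used to predict the
  held-out methylation row; a site is kept when its mean absolute LOO error
  divided by its SD across animals is below 0.5. The ratio rewards sites
  that are simultaneously variable and well explained; zero-variance sites
  are excluded and counted. Sample SD (n−1) is used throughout, and is
  configurable only in the sense that the code has a single definition.
* **Iterative trait filter** (`iterative_trait_filter()`, threshold 0.6).
  All current traits are LOO-predicted from the retained sites; every
  non-forced trait whose observed-vs-predicted Spearman falls below 0.6 is
  removed *simultaneously*, and the loop repeats until stable (at most
  n_traits iterations). Rank and the strain encodings are forced: they stay
  in the model regardless and are reported with their correlation. On
  synthetic data with planted glucose effects, this reliably ends at the
  three glucose timepoints plus the forced covariates, with rank around
  |ρ| ≈ 0.3 — it would be dropped if not forced.

Surviving sites are then tested one at a time by ordinary least squares of
methylation on the selected (standardized) traits (`fit_site_mlr()`), with
two-sided t-tests per slope. Coefficient-wise tests were chosen over a
whole-model F because significance is consumed per trait/site pair; the
residual-variance and df bookkeeping supports either. P-values are BH
adjusted within each trait across sites (`bh_adjust()`, wrapping
`p.adjust`), and site sets per trait are cut at adjusted p < 0.01 and merged
into blood-glucose and strain unions (`select_sites()`).

## Model 2: mortality network and elastic-net transfer

`build_feature_vectors()` turns longitudinal records into one vector per
animal/timepoint — food intake (kcal), body weight (g), fat and fat-free
mass (g), glucose (mg/dL), the strain pair, rank code and timepoint index —
with target `D = age_at_death − current_age` in weeks; incomplete records
are dropped and counted, and a record at the death timepoint (D = 0) is
valid.

The network (`train_mlp()`) is an input → 70 → 70 → 1 perceptron with ReLU
hidden activations and an affine output, trained with minibatch Adam
(lr 0.001, batch 32) on MAE loss. Two conventions are pinned:

* **Pass count.** One "epoch" is counted per training batch, so the number
  of passes over the data is `ceiling(n/32)` (`n_training_passes()`): 106
  passes for the full 3,390-vector cohort, ~85 for a 4/5 training split.
  `mlp_config(passes=)` overrides this.
* **Normalization.** Features are z-scored with statistics from the training
  split only, except strain, rank and timepoint, which stay on their
  categorical scales. Per-fold refitting of these statistics is what keeps
  cross-validation leak-free, together with animal-grouped folds
  (`grouped_kfold()`): all of an animal's vectors share a fold.

Weight initialization is the uniform fan-in scheme
(U(−1/√fan_in, 1/√fan_in) for weights and biases) under a fixed seed;
training is bit-reproducible given seed, data and config. There is no early
stopping and no learning-rate schedule.

Feature importance comes in two flavours. `importance_by_removal()` reruns
the full grouped CV once per excluded parameter (strain's two columns move
together), optionally with timepoint excluded everywhere — in that family
the timepoint-removed model is the control. `importance_by_scramble()`
trains once on all data and recomputes per-fold losses after replacing one
parameter's values with random draws: standard normal on the z-scored scale
for numeric traits, N(mean, sd) of the observed column for the exempt
categorical parameters (a case the training convention does not otherwise
define). Each variant's per-fold losses are compared with the control's by
Tukey–Kramer studentized-range tests with variance pooled across the family
(`tukey_bh()`, on `ptukey`), BH-adjusted. Per-fold mean losses (n = k) are
the units entering the comparison.

For the transfer, `predict_cohort_a()` applies the trained network (with
its stored normalization) to the methylation cohort's vectors;
`weighted_average()` collapses the per-timepoint predictions with the fixed
increasing schema w12 = 0.02 … M16 = 0.23 (step 0.03, sum 1) — later
timepoints dominate because the methylation assay follows the last
phenotyping — renormalizing over the present timepoints when some are
missing. Group trends in the averaged predictions are tested by Kendall
tau (`group_trend_tests()`; `cor.test` uses the exact null where sample
size and ties allow, asymptotic otherwise). `fit_elastic_net()` regresses
the averaged predictions on the full beta matrix under the objective
`(1/2n)·RSS + α·L1·Σ|β| + α(1−L1)/2·Σβ²` (glmnet's parameterization with
lambda = α, alpha = L1), grid-searching α ∈ {0.01, 0.033, 0.1, 0.33, 1} ×
L1 ∈ {0.1, 0.3, 0.5, 0.7, 0.9, 1} by 5-fold CV MAE — the grid contains 0.1
so the deposited-data optimum is reachable — then refits on all animals;
the nonzero coefficients define the aging site set. Beta values share a
scale, so predictors enter unstandardized by default.

## Integration

`intersect_sets()` computes exact pairwise and triple intersections and the
triple as a rounded percentage of the smallest set. `overlap_pvalue()`
scores the triple against a null of independently, uniformly drawn sets
from the array universe: the overlap under that null decomposes into a
chain of hypergeometric draws (the intersection of a uniform random set
with any fixed set of size m is hypergeometric), so each Monte-Carlo
replicate samples the chain directly with `rhyper` — distributionally
identical to drawing the sets and fast enough for 10⁵ replicates in well
under a second. The p-value is add-one smoothed,
`(1 + #exceed)/(1 + n_mc)`, so it is never zero. A conditional mode fixes
the observed two-set overlap and resamples only the third set.
`attribute_glucose_timepoints()` partitions the triple set by month-14/16
glucose membership, and `glucose_group_anova()` runs the one-way ANOVA of
glucose by rank-by-strain combination (degenerate all-equal input reports
F = 0, p = 1 by convention).

## The synthetic-data generator

`generate_cohort_a()` and `generate_cohort_b()` emulate the two cohorts
with planted, recoverable effects; every default is a study condition, not
a tuning knob. Cohort A defaults to 46 animals with strain proportions
18/12/16 and glucose measured at months 6, 14 and 16; planted CpG sites are
affine in one driving trait, `clip(base + 0.1·z(trait) + N(0, 0.02), 0, 1)`
with the clip count logged — a 0.1 beta-unit shift per trait SD against
0.02 noise is a strong but realistic array effect, and is the
signal-to-noise regime at which the downstream filters are exercised.
Cohort B defaults to 345 animals over the 8-timepoint grid; age at death is
linear-Gaussian, `baseline 105 + Σ slope·driver + N(0, 4)` weeks, floored
one week past the last measurement — the simplest model whose parameters
the network can provably recover, with an OLS fit on the generating
features as the natural oracle. Default slopes give glucose (−6), fat mass
(−4) and fat-free mass (+5) the strongest trait effects and order the
strains C57BL/6J > CD1 > Sv129Ev in remaining lifespan (slopes 2 and 6 on
the two encodings), matching the direction of the strain mortality gradient
the models are meant to detect; rank adds +2 weeks per level. Rank is
assigned uniformly within strain by default, with an "observed" preset
reproducing the deposited pattern in which no CD1 animal is subordinate.
Trait records drift with age around each animal's latent level (body mass
up, glucose down) with 10% measurement noise.

What the generator does *not* emulate: genomic autocorrelation of
methylation, multi-driver sites (each planted site has exactly one driving
trait, so the glucose and strain site sets are disjoint and the three-way
overlap of a default run is empty — the enrichment statistic is therefore
validated at the deposited set sizes instead), hazard-shaped mortality, or
the stress protocol itself. Passing tests on this generator show the
machinery is correct and sensitive at a known SNR; they do not certify
performance on real array data.

## Numerical choices and test-scale conventions

* Pseudoinverse cutoff: `max(dim)·eps·max(d)`; Spearman ties by average
  ranks; simultaneous (not one-at-a-time) removal per trait-filter pass.
* Missing trait cells drop the animal from Model 1 (complete-case, logged);
  the mortality network instead drops individual records.
* Elastic-net CV folds are plain animal folds (one row per animal at that
  stage); ties on the CV grid resolve to the first (most-regularized-last)
  entry deterministically.
* The test suite and examples run cohorts at reduced sizes. Because the
  pass-count convention scales with n, small cohorts get few Adam updates
  at lr 0.001; property tests of the importance and transfer machinery
  therefore run the network at lr 0.01, where it converges at a few hundred
  vectors — the study-condition lr 0.001 remains the default and is used
  for the full-scale (345-animal) cross-validation check, which lands
  within 1.2× of the OLS oracle. Problem sizes used by the tests: 400–2,000
  sites, 46 animals for cohort A; 100–345 animals for cohort B; 10⁵
  Monte-Carlo replicates for the enrichment test.
* Seeds: every stochastic function takes an explicit seed; internal
  sub-seeds are derived deterministically and kept below 2³¹.

## Known limitations

The masked-correlation collinearity procedure is order-dependent by design
(that is what makes it reproducible) and the literal signed-threshold
reading will not prune strong *negative* redundancy unless `use_abs` is
set. The network is a plain MLP over per-timepoint vectors — longitudinal
sequence models are out of scope. The elastic-net site set inherits the
instability of correlated-predictor selection at n = 46; the recovery
property (≥60% of planted sites on average) is asserted at the planted
collinearity structure and will not transfer to arbitrary designs. The
enrichment null treats the three sets as independent uniform draws, which
ignores the shared site-filtering upstream; the conditional mode exists for
that reason.
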
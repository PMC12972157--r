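# methspan

Linking healthspan traits, liver DNA methylation, and mortality risk in mice
under lifelong chronic social stress.

`methspan` implements a two-model analysis pipeline for cohorts of socially
stressed mice in which one arm carries deep longitudinal phenotyping plus a
liver methylation array (cohort A, 46 animals) and the other carries
longitudinal phenotyping followed to natural death (cohort B, 345 animals):

**Model 1 — trait ↔ methylation.** The beta matrix `M` (animals × CpG sites)
is modelled as a linear map of standardized traits, `M = T C`: with a
bias column appended to the trait matrix `T`, the site coefficients are
`C = pinv(T) M`, predicted methylation is `M_pred = T C`, and traits are
inversely predicted as `T_pred = M pinv(C)`. Around this fit sit three
filters: a Spearman collinearity mask over the trait set (threshold 0.7; rank
and strain protected), a leave-one-out per-site predictability filter
(`MAE/σ < 0.5`), and an iterative inverse-predictability trait filter
(Spearman ≥ 0.6, rank/strain forcibly retained). Surviving sites are then
tested per site by multiple linear regression `y = β₀ + Σ βx + ε` with
Benjamini–Hochberg adjustment within trait, yielding blood-glucose and strain
site sets.

**Model 2 — mortality network and epigenetic transfer.** A multilayer
perceptron (input → 70 → 70 → 1, ReLU hidden layers, Adam at lr 0.001, batch
32, MAE loss, one pass per batch of the training data) predicts weeks until
death `D = age_at_death − current_age` from per-timepoint feature vectors,
validated by animal-grouped 5-fold cross-validation, with feature importance
by ablation retraining and by validation-time scrambling
(Tukey–Kramer + BH). The trained network is transferred to cohort A, its
per-timepoint predictions collapsed by the increasing weight schema
(w12 = 0.02 … M16 = 0.23), and the averaged mortality predictions regressed
on the full beta matrix by elastic net
(`(1/2n)·RSS + α·L1·Σ|β| + α(1−L1)/2·Σβ²`, grid-searched by CV MAE) to select
aging-associated sites.

**Integration.** The glucose, strain and aging site sets are intersected;
the three-way overlap is scored by a Monte-Carlo enrichment test against
independent uniform draws from the array universe, attributed to glucose
timepoints, and complemented by one-way ANOVA of glucose by rank/strain
group.

A seeded synthetic-data generator (`synth_config()`, `generate_cohort_a()`,
`generate_cohort_b()`, `generate_site_mapping()`) plants known trait–CpG and
trait–lifespan effects so that every stage is testable offline.

## Worked example

```r
library(methspan)

cfg <- synth_config(n_animals_A = 46, n_sites = 400,
                    planted_glucose_sites = 40, planted_strain_sites = 40,
                    n_animals_B = 345, seed = 11)
res <- run_pipeline(cfg, mlp_config(), n_mc = 1e4)
subset(res$trait_filter, retained)
```

```
                      trait   spearman retained forced
1   M6_aging_phase_GLU_mgdl  0.9954363     TRUE  FALSE
2  M14_aging_phase_GLU_mgdl  0.9960530     TRUE  FALSE
3  M16_aging_phase_GLU_mgdl  0.9950663     TRUE  FALSE
17                rank_code -0.3725014     TRUE   TRUE
18          strain_b6_or_sv  0.7607387     TRUE   TRUE
19         strain_cd1_or_b6  0.8251370     TRUE   TRUE
```

The iterative filter keeps exactly the three glucose timepoints plus the
forced rank/strain covariates; rank alone reaches Spearman ≈ −0.37 and would
be dropped if not forced — the same qualitative outcome the procedure is
designed to produce on real data. Further down the same run:

```
sites passing MAE/sigma < 0.5: 80 of 400
glucose set: 40 sites; strain set: 40 sites
grouped-CV MAE (weeks): 3.69 4.33 3.96 3.9 3.94 | mean 3.96
enet_fit: alpha = 0.1, l1 = 1, 5 sites selected, CV MAE = 3.574
overlap_result: sets glucose=40, strain=40, aging=5; triple = 0 (~0% of smallest)
```

All 80 planted sites (and none of the 320 noise sites) pass the MAE/σ
filter, and the per-site regressions recover both planted sets in full. The
mortality network's grouped-CV error (≈4 weeks) sits just above the 4-week
lifespan noise floor of the generator. The three-way overlap is empty here
because the generator plants each site with a single driver, so the glucose
and strain sets are disjoint by construction (see the vignette).

The enrichment test itself, at the study's deposited set sizes:

```r
overlap_pvalue(284860, c(89, 11026, 9363), 32, n_mc = 1e5, seed = 1)
#> [1] 9.9999e-06   (null mean: 0.112 shared sites)
```

Thirty-two shared sites against a null expectation of ~0.11 is overwhelming
enrichment (p ≈ 1e-05, the smallest value resolvable at 10⁵ replicates).

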
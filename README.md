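# immunonoise

Residual-subspace anomaly detection for immunologic biomarker cohorts.

Early-onset, rapidly progressing periodontitis (EOP) differs from
late-onset disease (LOP) not only in mean immune-parameter levels but —
hypothetically — in *hidden random fluctuations* (noise, anomalies) that
destabilize the host response and drive exacerbation.  `immunonoise`
implements a complete, reproducible pipeline for finding such fluctuations
in a patient × parameter table of 28 continuous immunologic parameters
(neutrophil function, lymphocyte subsets, cytokine production, T-cell
blastogenesis, serum IgG titers against periodontal bacteria):

1. **Group comparison** — per-parameter Mann-Whitney U tests (EOP vs LOP).
2. **Residual subspace** — PCA of the parameter correlation matrix on the
   pooled discovery groups; components with eigenvalue > ε keep their
   dominant parameter (the *normal* subspace of overall susceptibility),
   the rest form the *residual* subspace where anomalies hide.
3. **Entropy screen** — per residual parameter, the plug-in sample entropy
   of recorded-value frequencies, H = −Σ (nᵢ/S) log₁₀(nᵢ/S), squared;
   for S = 111 discovery patients H² ranges over [0, 4.18], for the
   51-patient validation cohort over [0, 2.92]; parameters with H² ≥ 3
   are flagged.
4. **Clustering cross-check** — two-step clustering (seeded k-means
   pre-clusters, then agglomerative merging under the log-likelihood
   distance d(j,s) = ξⱼ + ξₛ − ξ⟨j,s⟩ with
   ξᵥ = −Nᵥ Σₖ ½ log(σ̂²ₖ + σ̂²ᵥₖ)); parameters that separate the two
   unsupervised clusters weakly (low normalized −log₁₀ p importance)
   corroborate the entropy flags.
5. **Classification** — per-patient aggregate Local Outlier Factor scores
   in the space of flagged parameters, then a k-NN vote on the scalar
   score with stratified 10-fold cross-validation, reporting sensitivity
   (EOP) and specificity (LOP).

A calibrated synthetic-cohort generator (28-parameter reference panel,
moment-matched normal / shifted log-normal marginals, recording-grid
rounding, an optional low-rank "collinear" correlation preset and an
explicit contamination model) makes every stage testable without patient
data.

## Worked example

Generate a structured cohort, identify the residual subspace, inject
hidden noise into five residual parameters, and recover it:

```r
library(immunonoise)

clean <- generate_cohort(default_table2_config(structure = "collinear", seed = 7))
clean
#> <cohort_table> 162 patients x 28 parameters
#>   groups: EOP=68, LOP=43, VALIDATION=51

discovery <- subset_by_group(clean, c("EOP", "LOP"))
decomp <- pca_subspace(discovery$values)
round(variance_explained(decomp, 11), 4)
#> [1] 0.9989
split <- split_subspaces(decomp, eps = 0.01)
length(split$residual_parameters)
#> [1] 17
```

Eleven components explain 99.9 % of the variance; the other 17 parameters
sit at eigenvalue ≈ 0 and form the residual subspace.  Now inject ±3-SD
bimodal contamination into 30 % of EOP patients for five residual
parameters and screen:

```r
targets <- c("chemotaxis", "CD4_pct", "CD8_pct", "CD20_pct", "IgG_Aa_ATCC29523")
cohort <- inject_contamination(clean,
  contamination_spec(targets, prop = 0.3, displacement = 3,
                     target_groups = "EOP"), seed = 8)
disc <- subset_by_group(cohort, c("EOP", "LOP"))

z <- standardize(disc$values[, split$residual_parameters])
importance <- predictor_importance(z, two_step_cluster(z, seed = 7))
head(importance[order(importance$importance), c("parameter", "importance")], 6)
#>         parameter importance
#>          CD20_pct  0.1833369
#>  IgG_Aa_ATCC29523  0.1950067
#>        chemotaxis  0.2572967
#>           CD4_pct  0.2678340
#>           CD8_pct  0.3970270
#>               IL1  0.6555319
```

The five contaminated parameters occupy five of the six lowest clustering
importance ranks — their group signal is diluted by the injected noise.
Scoring patients by aggregate LOF over those parameters and classifying
the scalar score:

```r
scores <- aggregate_lof(cohort, targets, k_lof = 10)
knn_classify_cv(scores$lof, scores$group, k_nn = 5, folds = 10, seed = 7)
#> <classification_report> k_nn = 5 , folds = 10
#>   apparent: sens 0.926 spec 0.814
#>   cv:       sens 0.926 spec 0.814
```

Cross-validated sensitivity 0.93 and specificity 0.81: patients carrying
injected fluctuations are recovered from their outlier scores alone.  The
full workflow (plus CSV/JSON reports and a run manifest) is available as
one call, `run_pipeline(config, output_dir)`, and from the shell via
`inst/scripts/immunonoise.R`.

## Package layout

- `R/` — cohort container and I/O, synthetic generator, group statistics,
  PCA subspace split, entropy screen, two-step clustering, LOF + k-NN,
  pipeline orchestration.
- `tests/testthat/` — unit, property and acceptance tests, including
  independent brute-force oracles for LOF, the log-likelihood distance
  and exact Mann-Whitney enumeration.
- `vignettes/residual-subspace-anomaly-detection.Rmd` — the methods
  vignette: model, assumptions, parameter choices, generator design and
  limitations.
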
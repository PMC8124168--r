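# lnradiomics

Radiomic prediction of **axillary lymph-node (ALN) status** from 3D
post-contrast breast-MRI lesion volumes.

ALN involvement is one of the main prognostic factors in invasive breast
cancer, yet it is currently established by invasive procedures (sentinel-node
biopsy, axillary dissection). This package implements, end to end, a
radiomics pipeline that predicts the binary node status non-invasively from
the primary lesion on a single subtracted post-contrast MRI volume together
with clinical and histological covariates:

1. **ROI pre-processing** — iterative 3D convex-hull smoothing of the
   segmentation label map with 26-connectivity merging; degenerate
   sub-volumes are dropped as outliers; the ROI-volume/hull-volume ratio
   becomes a shape feature.
2. **Feature computation** — 257 features per lesion: 12 first-order
   histogram measures; 182 GLCM3 textures (7 measures on the 3D grey-level
   co-occurrence matrix for each of the 26 unit displacements of
   {−1,0,1}³ \ {0}); 48 TOP-LBP features (local binary patterns on the
   three orthogonal planes through the ROI centroid, in plain, uniform,
   rotation-invariant and uniform+rotation-invariant codings, P = 8,
   summarized by the first-order measures); the hull volume ratio; and 14
   encoded semantic fields (with ER/PgR > 10%, HER2 > 2+, Ki67 > 14%
   receptor cut-offs and the Luminal A/B / HER2 / TN class derivation).
3. **Signature selection** — a wrapper: best-first subset search scored by
   random-forest AUC under inner 5-fold CV, nested in an outer 10-fold CV
   whose test folds the search never sees; the signature keeps features
   selected in ≥ 20% of outer folds.
4. **Classification** — a cost-sensitive random forest (FN cost 0.59, FP
   cost 0.41, realized as per-class instance weights plus the cost-optimal
   decision threshold t\* = 0.41) under stratified 10-fold CV, reported as
   pooled out-of-fold ROC/AUC (Mann–Whitney), confusion counts in both
   class orientations, and accuracy with Wilson / AUC with DeLong 95%
   intervals.

No patient data are included. A seeded synthetic-cohort generator produces
textured ellipsoidal-to-spiculated lesions whose texture statistics differ
by class by a controllable effect size, plus semantic tables drawn from the
published category frequencies and the 27-positive/72-negative cohort
imbalance — so the whole pipeline is testable offline, including
planted-signal recovery.

## Worked example

```r
library(lnradiomics)

spec    <- cohort_spec(n_cases = 60, positive_fraction = 27/99,
                       texture_effect = 2, grid_shape = c(20, 20, 20),
                       seed = 42)
cohort  <- simulate_cohort(spec)        # tibble: volumes, masks, semantics
features <- extract_features(cohort)    # 60 x 259 (case_id + 257 + label)

sig <- nested_selection(
  features,
  wrapper_config(outer_folds = 5, num_trees = 50, seed = 1),
  features = c("fo_sd", "fo_entropy", "glcm3_homogeneity_(1.0.0)",
               "volume_ratio", "age", "histotype", "max_diameter",
               "lbp_energy_RI"))
sig
#> <ln_signature> 7 feature(s), threshold 0.20 over 5 outer folds
#>   fo_entropy                   80%
#>   fo_sd                        60%
#>   glcm3_homogeneity_(1.0.0)    60%
#>   age                          40%
#>   histotype                    40%
#>   max_diameter                 40%
#>   volume_ratio                 40%

ev <- cost_sensitive_cv(features, sig$features, folds = 10,
                        num_trees = 500, seed = 2)
ev
#> <ln_cv_eval> n = 60, AUC = 0.743, accuracy = 0.717
#>   confusion (positive = node-positive): TP 8  FP 9  TN 35  FN 8
glance(ev)
#>   tp fp tn fn accuracy accuracy_lo accuracy_hi   auc auc_lo auc_hi
#> 1  8  9 35  8    0.717       0.592       0.815 0.743  0.593  0.893
```

The signature recovers the planted texture features (`fo_entropy`,
`fo_sd`, GLCM homogeneity) with high selection frequencies — the cohort was
simulated with a planted texture effect, so texture, not the semantic
fields, carries the class signal. The cross-validated AUC of 0.74 on 60
cases reflects that planted separation; `autoplot(ev)` draws the pooled
out-of-fold ROC curve and `autoplot(sig)` the selection-frequency profile.

A thin command-line front end over the same functions lives in
`inst/cli/lnradiomics.R` (subcommands `simulate`, `preprocess`, `extract`,
`select`, `classify`, `ablate`), reading/writing NIfTI volumes, CSV feature
tables and JSON signatures/reports.

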
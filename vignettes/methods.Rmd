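---
title: "Methods: radiomic prediction of axillary lymph-node status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic prediction of axillary lymph-node status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling pipeline

Axillary lymph-node (ALN) involvement is a central prognostic factor in
invasive breast cancer, but it is established by invasive procedures
(sentinel-node biopsy or dissection). `lnradiomics` implements a
radiomics pipeline that predicts the binary ALN label from the primary
lesion as seen on a single post-contrast (subtracted, second-phase)
breast-MRI volume, combined with clinical and histological covariates.
The pipeline has four blocks:

1. **ROI pre-processing** — iterative convex-hull smoothing of the
   manual segmentation mask;
2. **feature computation** — 12 first-order, 182 GLCM3 and 48 TOP-LBP
   quantitative features plus one hull volume ratio and 14 encoded
   semantic features (257 in total);
3. **signature selection** — a wrapper (best-first search scored by
   random-forest AUC under inner 5-fold CV) nested in an outer CV loop,
   with a 20% selection-frequency stability rule;
4. **classification** — a cost-sensitive random forest under stratified
   10-fold CV, reported as ROC/AUC, confusion counts and accuracy with
   95% intervals.

Because no patient images ship with the package, a seeded
synthetic-cohort generator reproduces the statistical structure the
pipeline assumes, and every stage is validated against brute-force
oracles and planted-signal recovery experiments.

## ROI pre-processing

Manual segmentations exported slice by slice have coarse boundaries, and
neighbourhood-based texture measures are sensitive to them. The mask is
therefore smoothed: its 26-connected components are each replaced by
their rasterized 3D convex hull; hulls that touch (26-adjacency) or
overlap are merged and re-hulled, iterating to a fixed point. Components
with fewer than 4 affinely independent voxel centers admit no 3D hull
and are dropped as outliers. The ratio

\[ \text{volume ratio} = \frac{|\text{kept original voxels}|}{|\text{hull voxels}|} \in (0, 1] \]

is itself a shape feature (1 for convex lesions, small for spiculated or
multifocal ones).

Numerical choices: hulls are computed in index space (voxel spacing is
metadata only); a voxel belongs to a hull when its center satisfies
every supporting half-space within `1e-9` (the hull is built by an
incremental insertion algorithm over the column-extreme candidate
points, which is exact for this purpose). The "too small to hull" rule
is operationalized as *fewer than 4 affinely independent centers*; the
ratio numerator uses the mask *after* outlier removal (both counts are
reported so the other convention can be recovered).

## First-order features

The in-ROI intensity histogram (by default one bin per grey level) is
summarized by 12 scalars: mean, standard deviation, skewness, kurtosis
(population moments; kurtosis non-excess), width (occupied grey-level
range), entropy (base 2, with $0\log 0 = 0$), energy
$\sum_b p_b^2$, the modal probability and its grey level, the energy in
a $\pm w$-bin window around the mode (default $w = 2$), the number of
strict relative maxima (plateaus do not count; edge bins compare to
their single neighbour), and the energy over the union of windows
around all relative maxima. Moments are computed on bin centers, which
equals raw-value moments at one bin per level.

## GLCM3 texture

For a displacement $d$, the 3D grey-level co-occurrence matrix counts
ordered in-ROI voxel pairs $(p, p+d)$; all 26 unit displacements
($\{-1,0,1\}^3$ minus the origin) are kept separately — matrices are
*not* symmetrized or pooled, and `glcm3(d)` is the transpose of
`glcm3(-d)`. Seven measures are computed per matrix on the normalized
probabilities: autocorrelation, homogeneity (inverse difference),
entropy, energy, covariance, inertia and absolute contrast — giving
$26 \times 7 = 182$ features named `glcm3_<measure>_(dx.dy.dz)`.

A literal co-occurrence matrix at the acquisition bit depth (16-bit MRI)
would be a $65{,}536^2$ matrix, statistically empty and infeasible;
volumes are therefore re-quantized to a working bit depth of 6 bits
(64 levels, configurable) by linear min–max scaling over the in-ROI
intensities — the customary radiomics resolution of this gap. Both pair
endpoints must lie inside the ROI. Directions with zero valid pairs
emit all-zero sentinels with a warning.

## TOP-LBP texture

A planar local binary pattern codes each pixel by comparing it with
$P = 8$ neighbours on a radius-$r = 1$ circle (bilinear interpolation
for off-grid samples; a neighbour strictly brighter than the center
sets its bit; ties code 0; bits are read counter-clockwise from angle
0). Three coding variants supplement the plain $2^P$ codes: uniform
(U; codes with more than two circular 0–1 transitions pool into one
bin; 59 bins at $P=8$), rotation-invariant (RI; minimal circular
rotation; 36 bins), and U+RI (10 bins). These bin counts are verified
in the tests by exhaustive enumeration of all 256 codes.

The three orthogonal planes through the ROI centroid (axial, coronal,
sagittal) are each coded; histograms are restricted to in-mask coded
pixels and concatenated in fixed plane order. The feature block applies
the 12 first-order measures to each variant's histogram, giving
$12 \times 4 = 48$ features. Two interpretive decisions were open and
are fixed here: (i) the 48 features arise as *12 measures × 4 variants*
(the variant-suffixed feature names, e.g. "Range U RI", support this
reading); (ii) the measures use the *code-aligned* histogram pooled
across the three planes, so that a constant volume — one code
everywhere — occupies a single bin and has zero range; the per-plane
concatenated histograms remain available from `toplbp_histograms()`.
Histograms are raw counts (not normalized per plane). Only the three
central planes are coded, following the "planes crossing the center of
the volume" construction; helicoidal 3D LBP neighbourhoods are out of
scope.

## Semantic encoding

Fourteen covariates form the semantic block: age, menopausal status,
hormone therapy, familiarity (0/1/>1 affected relatives), lesion
localization, margins, maximum diameter (mm), kinetic curve type
(I/II/III), histotype (IDC/ILC/medullary), grading, molecular tumor
class, and ER/PgR/HER2 positivity. Receptor flags use the diagnostic
cut-offs as strict inequalities: ER+/PgR+ when expression > 10%, HER2+
when score > 2+, Ki67-high when > 14%. The tumor class is derived with
documented precedence (TN first, then HER2-overexpressed, then Luminal
A/B, with ER+HER2+low-Ki67 and the rare ER−/PgR+ pattern coded Luminal
B); a provided class that contradicts the derived one wins with a
warning. The exact 14-field roster is an inference from the published
counts (Ki67 is absorbed into the tumor class); it covers every
collected field and reproduces the count. Nominal fields are
label-coded integers rather than one-hot vectors because the downstream
learner is a tree ensemble that handles qualitative features directly.

## Synthetic cohorts

The generator emulates what the pipeline needs to be testable, not MR
physics. Lesions are axis-aligned ellipsoids (semi-axes ~1/7 to ~1/5 of
the grid) plus a Poisson number (mean 3) of radial spicules, kept ≥ 2
voxels from the grid edge so unit-displacement lookups stay in bounds.
In-mask intensity is a base level (55% of the grey range) plus
Gaussian-correlated noise standardized *over the mask*, so the planted
class-conditional standard deviation and correlation length are exact:
node-positive lesions get their noise s.d. scaled by
$1 + 0.15\,e$ and correlation length by $1 + 0.30\,e$ for texture
effect $e$ ($e = 0$ plants nothing). The background is low-level
i.i.d. noise; volumes are quantized to 8 bits in arbitrary units (the
subtracted-phase intensities of the source modality are not
standardized, so no physical unit is claimed).

Semantic records draw categorical fields from the published cohort
marginals (histotype 83.8/12.1/4.0%, menopause 57.6%, and so on);
localization, for which no frequencies were published, uses a fixed
plausible distribution. Age is a truncated normal on 37–82 years (mean
55.5); diameters are log-normal around 22 mm. Immunohistochemistry
values are drawn consistently with the sampled tumor class so encoding
round-trips without warnings. A positive `semantic_effect` raises the
log-odds of ductal histology for node-positive cases by $0.8\,e$,
planting a label dependence in exactly one semantic field. The default
cohort is 99 cases with 27 positives, the published imbalance.

What the generator does **not** emulate: coil/bias fields, dynamic
phases, necrosis, multifocal or bilateral lesions, inter-scanner
variation, or realistic correlations between semantic fields (age and
menopause are drawn independently). Passing tests therefore demonstrate
the pipeline's correctness and its ability to recover planted signal —
not clinical performance on real cohorts.

## Wrapper selection

Subsets are scored by the mean out-of-fold AUC of a probability random
forest over 5 stratified inner folds. The search is forward best-first
with backtracking: the best open node is expanded by single-feature
additions, and the search stops after 5 consecutive expansions without
improving the global best (improvement margin $10^{-6}$); ties prefer
smaller subsets, then lexicographic order, which resolves duplicated
predictors to a single copy. Scores are cached so each subset is
evaluated once. The outer loop (10 stratified folds; only the training
split is ever passed to the search, and the held-out ids are recorded
as an audit trail) yields per-fold subsets; the signature keeps
features selected in ≥ 20% of folds. An empty signature at the
threshold is an error suggesting a lower threshold rather than a silent
fallback.

The evaluator's hyperparameters default to the ranger library defaults
(500 trees); the original study's forest defaults are not recoverable,
so the values actually used are pinned in `wrapper_config()` for
reproducibility. The simulation studies in the tests and acceptance
script use 50-tree forests and pools of 12 features at 200 cases —
sizes chosen to give stable planted-signal recovery across 10 seeded
replicates while keeping the full suite re-runnable on one CPU.
Stratified folds are used throughout: with a 27/72 imbalance,
unstratified 10-fold splits would regularly produce single-class folds
and undefined AUCs.

## Cost-sensitive classification

Class imbalance is addressed by a misclassification-cost matrix
(FN cost 0.59, FP cost 0.41, zero on the diagonal; the FN cost is ~50%
higher because a missed nodal metastasis forfeits treatment whereas a
false alarm costs an unnecessary work-up). The mechanism named by the
cost matrix is realized with two pinned knobs: per-class instance
weights proportional to the cost of misclassifying that class, and hard
labels from the expected-cost-minimizing threshold
$t^* = c_{FP}/(c_{FP}+c_{FN}) = 0.41$ on the positive-class score
(strictly greater; at equality the prediction is negative). With equal
costs the implementation passes no weights at all, so it reduces
*exactly* to the unweighted forest with the 0.5 threshold. Partitions
for classification are seeded independently of the selection folds.

Evaluation pools the out-of-fold scores into a single ROC; the AUC is
computed by the Mann–Whitney construction (ties count ½) and equals
the trapezoidal area, which the tests verify against an $O(n^2)$
pair-counting oracle and the independent pROC implementation. Accuracy
gets a Wilson 95% interval and the AUC a DeLong 95% interval — the
interval methods are this package's choice, as the source report does
not name one. Confusion counts are reported in both orientations
(node-positive as positive, and the majority node-negative class as
"positive"), because published tables use the latter convention.

## Problem sizes and determinism

Default simulation sizes used by the test-suite and the acceptance
script: oracle fixtures at $8^3$–$10^3$ voxels; single-case checks on
$16^3$–$28^3$ grids; cohort experiments at 200 cases on $20^3$ grids;
recovery experiments over 10 (tests) or 5 (acceptance script) seeded
replicates. Every stochastic step takes an explicit seed, and stage
seeds are derived from one base seed by an integer scramble kept below
$2^{31}$; identical spec + seed reproduces cohorts, signatures and
evaluations bit for bit (verified in the tests).

## Known limitations

* The hull is computed in index space; anisotropic voxel spacing is
  carried as metadata but does not influence the geometry.
* NIfTI is the only volume format read and written.
* Selection with all 257 features at ranger defaults is computationally
  heavy (hours, not minutes); the package exposes the candidate-pool
  and tree-count knobs rather than silently subsampling.
* The synthetic generator's texture model controls first- and
  second-order statistics directly but is far simpler than real
  enhancement patterns; real-data performance claims are out of scope.
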
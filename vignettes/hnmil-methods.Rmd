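---
title: "Attention-MIL outcome prediction from head-and-neck CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-MIL outcome prediction from head-and-neck CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pretreatment CT is acquired for essentially every head and neck squamous
cell carcinoma (HNSCC) patient, and the primary gross tumor volume (GTVp)
is delineated for radiotherapy planning. `hnmil` implements a complete,
tested pipeline for predicting dichotomized 2-year outcomes — overall
survival (OS), locoregional control (LRC) and freedom from distant
metastasis (FFDM) — from CT + GTVp pairs, using attention-based multiple
instance learning (MIL) over per-slice (or per-subvolume) feature
embeddings, benchmarked against a handcrafted radiomics baseline, a
clinical covariate baseline and a multimodal fusion of the two, with a
full evaluation stack (bootstrap AUROC confidence intervals, paired score
permutation tests, Kaplan-Meier/logrank/Cox risk stratification,
correlation analysis, Benjamini-Hochberg adjustment).

Because real HNSCC imaging cohorts are access-restricted, the package
ships a synthetic phantom cohort generator that reproduces the statistical
structure the analysis relies on. Everything downstream of the generator —
preprocessing, feature extraction contracts, the MIL transformer, the
selection chain, the statistics — is exactly the machinery one would run
on real NIfTI CT + GTVp data.

## The phantom cohort generator

`generate_cohort()` draws, per patient:

* a body phantom: a soft-tissue ellipsoid (~30 HU) in air (−1000 HU) on a
  64×64×48 voxel grid with anisotropic spacing (1, 1, 2) mm, plus a flat
  high-HU bed slab deliberately disconnected from the body so that body
  masking by connected components is genuinely exercised;
* an ellipsoidal GTVp with semi-axes uniform in 8–15 mm at ~50 HU, carrying
  Gaussian HU noise whose standard deviation (uniform in 10–60 HU) is the
  intra-tumor *texture heterogeneity* parameter;
* a latent log-hazard `risk = 1.0·z(log volume) + 0.8·z(texture) +
  0.3·(N − mean N)`; nodal stage N is drawn from an ordered-logit whose
  location increases with the volume/texture part, so N stage is both a
  consequence and an independent amplifier of risk, mirroring how nodal
  burden behaves clinically;
* per-endpoint event times `T ~ Exp(0.02·exp(risk))` per month with
  independent censoring `C ~ Exp(0.01)`; the exponential
  proportional-hazards form is the simplest generator under which Cox
  hazard-ratio recovery is well defined;
* clinical covariates (age, sex, T stage linked to volume, HPV status,
  chemotherapy) with missingness completely at random at rate 0.05, to
  exercise the mode/mean imputation; a persistent-disease flag with
  probability 0.05 exercises the LRC exclusion rule.

The defaults above were fixed once as the package's study conditions. With
them, roughly 40–45% of patients experience an OS event within the 24-month
horizon and 10–20% are excluded as lost to follow-up — a deliberately
signal-rich regime appropriate for testing recovery, not a calibrated
epidemiological model. The true risk yields a test-cohort AUROC ceiling of
roughly 0.84; an image model can only recover the part of that signal that
survives embedding.

What the phantoms deliberately do **not** emulate: real anatomy, DICOM
acquisition artifacts, multi-lesion disease, inter-scanner effects, or
informative censoring. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted signal — they are not evidence
about performance on clinical data.

## Endpoint dichotomization

`dichotomize_endpoint()` labels patients at the 24-month horizon: events on
or before the horizon are positive; event-free follow-up past it is
negative; censoring before the horizon is excluded ("lost to follow-up");
same-day events are excluded as ambiguous; patients with persistent disease
are excluded from LRC. Only these adjudication rules are implemented; other
forms of ambiguous endpoint data are out of scope.

## Preprocessing

* **Body masking** (`mask_body()`): threshold at −500 HU, keep the largest
  3D connected component (6-connectivity), fill internal cavities, and set
  everything outside to −1024 HU. This replaces a learned body segmenter
  with a threshold contract that removes the bed identically on phantoms.
* **Resampling** (`resample_isotropic()`): separable per-axis interpolation
  to 1 mm isotropic — linear for CT, cell-membership nearest for the mask —
  under the cell-extent convention (`n_out = round(n_in·spacing/target)`),
  so 50 voxels at 2 mm become exactly 100 at 1 mm and identity spacing is a
  bit-exact no-op.
* **Windowing** (`window_hu()`): soft-tissue window, level 50 HU, width
  120 HU, clipped and affinely scaled to [0, 1]. For the 3D route,
  `normalize_3d()` instead maps [−1024, 2048] HU to [0, 1].
* **2D bags** (`extract_view_slices()`): every slice index where the mask
  is present, per requested view (axial, or all three), cropped to 224×224
  centered at the in-plane projection of the 3D GTVp center of mass
  (rounded half-up), zero-padded at borders.
* **3D bags** (`sample_subvolumes()`): 100 centers from an isotropic
  Gaussian with variance 16 voxels² around the GTVp center of mass, rounded
  and clamped (not rejected, so exactly n instances survive), 50³ boxes.

## Feature extraction and augmentation

Extractors are pluggable: any object with `input_kind`, `embedding_dim` and
a `map()` closure satisfies the contract; an adapter for a real pretrained
foundation model owns its own input normalization and plugs in unchanged.
The shipped `toy_extractor()` is deterministic: each instance is pooled to
a fixed coarse grid of per-block means *and* per-block standard deviations
(16×16×2 for patches, 10³×2 for subvolumes), flattened, passed through a
seeded fixed random linear projection and a tanh. The dispersion channel
exists because block means alone attenuate intra-tumor texture variance by
the block width, which would leave the embedding blind to the generator's
texture-risk component; with it, both mean-intensity and variance
differences provably move the embedding.

Augmented twins are built in image space (`augment_patch()`): a rotation
with angle uniform in [0°, 10°] (bilinear, zero fill, verified against
EBImage's implementation) is always applied, a σ = 1 px Gaussian blur with
probability 0.5. The rotation angle is sampled once per instance at
extraction time, matching a precomputed-features workflow. Subvolumes are
rotated in-plane slice-wise by one shared angle.

## The MIL transformer

The model (`mil_forward()`, trained by `train_mil_cv()`) is a small
pre-norm transformer written directly in R matrix algebra with hand-derived
backpropagation (checked against central finite differences in the test
suite at relative error < 1e-4):

1. linear input projection of the N×D bag to `model_dim`;
2. `n_layers` blocks of (LayerNorm → multi-head self-attention → residual;
   LayerNorm → 2×-wide ReLU FFN (+ optional dropout) → residual);
3. attention pooling: per-instance scores `s_i = v'tanh(W h_i + b)`,
   softmax weights `a = softmax(s)`, bag representation `Σ a_i h_i`;
4. sigmoid head → patient-level probability, with the attention weights
   exported per instance.

Pooling by softmax attention makes the score exactly invariant to instance
order and assigns uniform weights to identical instances — both are tested
exactly. The topology defaults (`model_dim` 512, 2 layers, 8 heads,
learned-query attention pooling) are declared package choices, all
configurable.

**Training protocol.** Class-stratified k-fold cross-validation (default
five folds, per-class round-robin after a seeded shuffle, so fold class
counts are within one sample of the cohort proportions). Per epoch and per
bag, the augmented twin is fed with probability 0.5; holdout evaluation
always uses plain features. The loss is binary cross-entropy weighted by
inverse class proportions. The optimizer is ADAM with first-moment decay
0.95 and cosine-annealed learning rate; checkpointing keeps the weights
with the lowest holdout loss, with early stopping after `patience` epochs
without improvement. Deployment selects the fold whose holdout AUROC is
closest to the median across folds, ties to the lowest fold id. All
randomness derives from one seed (default 1337), so fold assignment,
initialization and augmentation coins are bit-reproducible.

Three numerical decisions deserve note:

* The configuration carries two learning rates: a 1e-3 initial rate
  (`lr_initial`) and a 1e-4 peak (`lr_max`). The package default anneals
  from the conservative 1e-4 peak over 64 epochs. The phantom-study runs in
  the tests and the acceptance script train for only 10 epochs and anneal
  from the 1e-3 rate instead, because a 6×-shorter schedule at 1e-4 leaves
  the model at the trivial all-0.5 plateau.
* Instance embeddings are standardized per dimension with statistics
  frozen from the fold-training bags. The toy embeddings (like pooled
  foundation-model features generally) share a large common offset; without
  this normalization the optimizer spends its budget on the shared
  component. The radiomics and clinical baselines z-score their inputs for
  the same reason.
* Batches (default 32 bags) are implemented as gradient accumulation over
  single-bag forward/backward passes, which is algebraically identical to
  padded batching and avoids masked-attention bookkeeping.

## Handcrafted radiomics baseline

A documented subset of IBSI-style features from the resampled CT/GTVp
(PyRadiomics parity is not claimed): shape (volume, exposed-face surface
area, sphericity `(36πV²)^{1/3}/A`, maximum 3D diameter between surface
voxel centers), first-order statistics (mean, variance, skewness,
kurtosis, energy, fixed-bin-width histogram entropy at 25 HU, 10th/90th
percentiles, min, max) and GLCM texture (contrast, dissimilarity,
homogeneity, joint entropy, correlation) from one symmetric normalized
co-occurrence matrix aggregated over the 13 unique 3D directions at
distance 1, with 16 equal-width gray levels. Degenerate single-level
regions return contrast 0 and correlation 1 by convention.

The selection chain: drop near-zero-variance features; z-score;
average-linkage hierarchical clustering on `1 − |Spearman ρ|` cut at 0.20;
keep per cluster the member with the highest mean absolute Spearman
correlation to its co-members; rank by mRMR in the difference (MID) form
(relevance = |point-biserial with the label|, redundancy = mean |Spearman|
with already-selected); keep `k = max(1, floor(n_minority/10))`. Bin
width, gray levels and distance are declared configuration defaults,
recorded in the function signatures and in the selection trace. Absolute correlations are used for
the representative rule. The selected features feed an unpenalized
logistic model whose standardization parameters are frozen at training.

## Clinical and multimodal models

Missing clinical values are imputed by training-set mean (numeric) or mode
(categorical, ties broken deterministically), with parameters frozen for
test cohorts. The design matrix uses age, sex, chemotherapy, T/N stage as
ordinal integers (dummy coding available), and HPV status dummy-coded
against the "negative" reference. The clinical baseline is a logistic
regression with balanced class weights (`n/(2·n_c)`); the multimodal model
appends the MIL score as one numeric column. `multivariate_lor()` reports
unpenalized log-odds ratios with Wald 95% CIs, flagging collinear columns
(rank-deficient fits) and apparent separation instead of diverging
silently. The "non-HPV-positive" subgroup keeps HPV-negative *and*
HPV-unknown patients — in registry data HPV status is unknown for a large
fraction of patients, and dropping them would shrink the subgroup far below
its intended size — and the rule is configurable.

## Evaluation statistics

* `auroc()`: Mann-Whitney form, ties counted one half.
* `bootstrap_auroc_ci()`: 1000 class-stratified bootstraps, percentile
  2.5/97.5 interval (percentile rather than BCa, matching an "empirical
  distribution" description).
* `permutation_auroc_test()`: paired scores on identical patients; under
  the null each patient's two scores are swapped independently with
  probability 1/2; p-value with the +1 finite-resampling correction. Other
  permutation schemes for paired model scores exist; this one is the
  package's declared choice and is isolated behind this one function.
* Kaplan-Meier, logrank and Cox (Efron ties) delegate to the survival
  package behind the module surface; tests verify them against a
  brute-force product-limit computation and a direct partial-likelihood
  grid maximization.
* `stratify_by_median()`: cutoff = training-cohort median score; strictly
  greater scores are high-risk (ties to low-risk); degenerate splits (one
  group, or events confined to one group) are flagged rather than forced,
  so downstream tables can report them as NA.
* Correlations: Spearman for ordinal/numeric variables, point-biserial for
  binary ones; Benjamini-Hochberg for multiplicity.

## The phantom study and what the numbers mean

`run_experiment()` wires the stages together with per-stage seeds derived
from one global seed. The acceptance script (`scripts/acceptance.R`) runs
the 2D-axial study at `n_train = 300`, `n_test = 200`, toy extractor
D = 128, MIL at `model_dim = 32`, one layer, four heads, 10 epochs — sizes
chosen so the whole study (including three permuted-label retrainings)
completes in minutes on one CPU while leaving the risk signal comfortably
recoverable. Under these conditions the deployed MIL model reaches a test
AUROC around 0.75 (true-risk ceiling ≈ 0.84), the radiomics baseline
around 0.84 (it reads tumor volume and HU variance directly, so it should
and does beat the embedding route on phantoms), and a label-permuted
control — the mean test AUROC of three models retrained on permuted
training labels — sits near 0.5. A single permutation retraining is a
noisy control (the fitted direction can align with the dominant risk axis
by chance), which is why the control averages three.

## Known limitations

* Phantom realism is intentionally minimal; absolute AUROCs here say
  nothing about clinical cohorts.
* The IBSI feature subset covers shape/first-order/GLCM only (no
  GLRLM/GLSZM/NGTDM, no filtered-image or peritumoral features).
* The transformer is CPU-sized; real foundation-model embeddings would
  warrant larger `model_dim` and the 64-epoch default schedule.
* One bag per patient; multi-lesion patients and PET are out of scope.
* The permutation scheme for AUROC differences and the exact transformer
  topology are declared package choices.
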
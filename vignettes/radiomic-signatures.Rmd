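---
title: "Network-based radiomic signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based radiomic signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Distinguishing benign from malignant sinonasal tumors on conventional MRI
is hard: morphological appearances overlap, and reading is
operator-dependent. Radiomics turns the segmented tumor volume into a
large panel of quantitative descriptors — first-order intensity
statistics, 3-D shape scores, and texture matrices (GLCM, GLRLM, GLSZM,
NGTDM, GLDM) — computed on the original image and on filtered versions of
it (Laplacian-of-Gaussian at several scales, wavelet sub-bands), per
acquisition (contrast-enhanced T1-weighted and T2-weighted). The result
is a wide, extremely redundant feature table (roughly 1200 variables per
modality for ~150 patients), plus a handful of categorical clinical and
radiological variables.

`radsig` implements the full analysis pipeline for such a cohort:

1. parsing of the extractor's naming dialect into per-column category
   metadata, and the two standardization schemes used downstream;
2. a synthetic cohort generator with the same statistical structure, so
   every stage is testable without patient data;
3. bias-corrected Cramér's V screening of clinical variables;
4. an unsupervised batch-effect audit (2-D embedding, density-based
   clustering, Fisher exact cluster enrichment);
5. DNetPRO network-based feature-signature extraction;
6. an MCC-based repeated cross-validation benchmark with Wilcoxon
   comparisons.

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` are thin narrative drivers over the functions documented
here.

## Data model and standardization

Feature names follow the extractor dialect
(`original_<family>_<Feature>`, `log-sigma-<s>-<s>-mm-3D_<family>_<Feature>`,
`wavelet-<XYZ>_<family>_<Feature>`); `parse_feature_name()` resolves
filter class, family and filter parameter, and
`canonical_feature_name()` inverts it exactly. Unknown prefixes are
treated as clinical covariates rather than rejected, so mixed tables load
cleanly.

Two scalings are used, for two purposes:

* **z-score** (`standardize(x, "zscore")`): subtract the column mean,
  divide by the *population* standard deviation (`sqrt(mean((x - mean(x))^2))`).
  Used inside every supervised fold. The population form was chosen (and
  is configurable in spirit — the difference is a factor
  `sqrt((n-1)/n)`) because the scaler is a fitted transform applied to
  held-out data, not an inferential estimate.
* **robust** (`standardize(x, "robust")`): subtract the median, divide by
  the interquartile range `Q3 - Q1` with linear-interpolation (type-7)
  quantiles. Used before unsupervised embedding, where heavy-tailed
  radiomic features would otherwise dominate. The same quantile rule is
  used everywhere a median or IQR is reported.

Columns with zero spread are mapped to all-zeros with a warning rather
than an error, so a cross-validation fold never crashes on a degenerate
column. Fitted `scaling_params` reapplied to the training data reproduce
the fitted output bit-for-bit, and are the only thing a held-out split
ever sees.

Clinical variables are categorical with an explicit missing marker.
Missing codes are imputed with the *training-split* mode
(`fit_clinical_encoder()` / `encode_clinical()`, which also emits an
imputation log); binary variables are integer-coded 0/1 and variables
with three or more levels (side, epicenter) are one-hot encoded before
any classifier sees them.

## The synthetic cohort generator

Real patient tables of this kind are not publicly depositable, so the
generator *is* the study condition, not a convenience:

* 145 patients, 52% malignant (76/69); two centers, 82%/18%, assigned
  independently of the outcome (so the joint center-by-tumor Fisher test
  is null by construction);
* per modality, feature blocks of 107 Original, 4 × 93 LoG and 8 × 93
  wavelet features, drawn from an equicorrelated Gaussian
  (common-factor construction) with within-block correlation 0.4 — a
  middle value for radiomic redundancy; 20 near-duplicate pairs
  (copy + noise, correlation ≈ 0.99) emulate the algebraically related
  feature pairs seen in real panels;
* planted informative features get a `+d` mean shift for the malignant
  class (default `d = 0.8` standardized units, 10 features in the CE
  T1-w LoG block, 10 in the T2-w Original block, 5 in each wavelet
  block — the per-modality category structure the benchmark should
  recover);
* clinical variables are sampled from class-conditional distributions
  solved (one-parameter exponential tilt, root-finding) so that their
  *population* Cramér's V hits the target while preserving the cohort
  marginal: 0.41 for symptoms, 0.38 for tumor size and gross adjacent
  site involvement, 0.10 for the remaining variables, for which no
  anchor exists; the five incompletely recorded variables get a 1%
  missing-at-random rate;
* a batch shift adds a constant (default 0.5 SD, a mild effect) to every
  radiomic column of center-B patients;
* an optional `n_xor_pairs` mode plants feature pairs that are
  individually null but jointly discriminative (class-dependent sign of
  the within-pair correlation) — the situation couple-based selection
  handles and single-feature screening cannot.

What the generator does **not** emulate: non-Gaussian marginals and
heavy tails, scanner-specific covariance structure beyond a mean shift,
deterministic algebraic relations between feature families, shape
features' discreteness, or label noise. Passing tests therefore
demonstrate correctness of the machinery and qualitative behaviour under
a realistic correlation/effect structure — not patient-level performance.

## Bias-corrected Cramér's V

For an `r × k` contingency table, `V = sqrt((χ²/n) / min(k-1, r-1))`
with the uncorrected Pearson χ². Because `V` is positively biased in
small samples, the screening reports the corrected version:

```
φ̃² = max(0, φ² − (k−1)(r−1)/(n−1))
k̃ = k − (k−1)²/(n−1),  r̃ = r − (r−1)²/(n−1)
Ṽ  = sqrt( φ̃² / min(k̃−1, r̃−1) )
```

`Ṽ ≤ V` always. Each variable is screened on its own complete cases
(listwise deletion across all variables would discard too much of an
incompletely recorded table); variables with a single observed level or a
constant outcome are reported as not computable rather than failing the
screen. No significance threshold is applied — the report is a ranking.
At `n = 500` the sampling SD of `Ṽ` is ≈ 0.035, so targets 0.41 and 0.38
are not reliably ordered at that size; only their separation from the
0.10 background is.

## The batch-effect audit

Features are robust-scaled, embedded in 2-D, clustered, and each pair of
clusters is tested for enrichment. Design choices:

* **Embedding**: the audit contract only requires a deterministic map to
  two dimensions that preserves gross structure; the stage is swappable.
  The default is a principal-component projection (with a fixed
  sign convention), which is deterministic, parameter-free and easily
  sufficient to expose mean-shift batch effects; neighbour-embedding
  methods would add stochasticity without changing any downstream
  contract.
* **Clustering**: `cluster_density()` implements hierarchical density
  clustering in the HDBSCAN style, written in-package: core distances at
  `k = min_cluster_size`, mutual-reachability distances, a single-linkage
  hierarchy, erosion of branches smaller than `min_cluster_size`, and
  excess-of-mass stability selection. Selecting the root is allowed, so a
  structureless cloud yields one cluster instead of an arbitrary split,
  and zero-height merges (exact duplicates) never split. Points that
  never join a stable cluster are noise (`-1`). Default
  `min_cluster_size = 5` (~3% of a 145-patient cohort).
* **Enrichment**: for every unordered pair of non-noise clusters the
  2 × 2 table (cluster membership × category level) is built from the two
  clusters' members only — the pairwise construction matches how pairwise
  cluster p-values are usually quoted — and tested with a two-sided
  Fisher exact test; noise points are excluded. Raw p-values are reported
  alongside Benjamini–Hochberg-adjusted ones (the adjusted values are
  what the planted-shift power checks use).
* The joint center × tumor Fisher test on the full cohort checks that
  center structure is not confounded with biology.

## DNetPRO signature extraction

The selection model: informative structure lives in *pairs* of features,
so every unordered couple is scored by the cross-validated MCC of a
linear SVM fit on just those two (standardized) columns; the top couples
form a weighted graph; connected components of that graph are candidate
signatures; each candidate is evaluated with an L2-penalized logistic
model, and the best component is the signature.

Parameter choices, all exposed in `dnetpro_config()`:

* **Couple metric**: MCC (accuracy available). Everything else in the
  pipeline is MCC, and the couple stage should not be blind to class
  imbalance either.
* **Couple CV**: stratified 5-fold, one fold assignment shared by all
  couples (so couple scores are comparable and an independent double-loop
  oracle can reproduce them exactly).
* **`keep_fraction = 0.05`**: the top 5% of couples become edges. A
  percentile rule (rather than a hard score threshold) keeps the network
  size stable across datasets; ties break by couple index so the retained
  set is deterministic. Increasing `keep_fraction` only ever adds edges.
* **Penalized logistic = ridge**: an L2 penalty of total-loss strength
  1.0 on standardized inputs (per-observation lambda `penalty/n`); the
  two names describe the same linear model family, and the package uses
  one implementation for both the component-evaluation and final
  classification steps.
* **`p_max = 2000`**: couple scoring is quadratic in the number of
  features; the pipeline mirrors the study design by pre-reducing to one
  radiomic category (plus clinical covariates) before DNetPRO, and
  refuses larger inputs with advice rather than hanging.
* Clinical covariates enter as ordinary nodes after encoding; they
  routinely emerge as hubs, which is itself a finding.

**Procedure A** runs the whole selection inside each outer training
split of a stratified cross-validation, refits the winner, scores it on
the outer test fold, and returns the *consensus* signature — the feature
set winning the most outer splits, ties broken by mean evaluation score;
its reported network comes from its best-scoring winning split. The
consensus rule is the package's own aggregation (any single-split choice
would be arbitrary).

**Procedure B** makes a stratified three-way partition: couples scored
and the network built on the training part, components *ranked on the
validation part*, the best component scored on the test part; the three
parts rotate through the roles, so each serves once in each (three
independent repartitions are available via `b_repartition`). With ~150
samples the three-way split leaves little data per role, which is why A
tends to dominate B — a tendency the acceptance checks reproduce.

A note on behaviour: when one feature is strongly discriminative, many
couples containing it score highly, it becomes a hub, and the top
component can be large. Recovery of planted features is therefore easy;
*compactness* of the signature is governed by `keep_fraction`.

## The benchmark harness

`repeated_stratified_cv()` evaluates a pipeline variant (all-features,
SVM-coefficient selection, DNetPRO A or B as a selector) with fresh
stratified fold assignments per repeat, derived from repeat-indexed
sub-seeds of one master seed — so variants run under the same master seed
share fold structure and can be compared with a *paired* Wilcoxon
signed-rank test (`compare_wilcoxon()`, midranks for ties, zero
differences dropped, rank-sum fallback for unpaired inputs). Everything
fitted — scaler, clinical imputation mode and encoding, selected
features, classifier — is fitted strictly inside the training fold.

MCC is computed with the zero-denominator convention (any zero factor →
score 0). Summaries are median ± IQR with the same type-7 quantiles as
the robust scaler. `run_benchmark()` evaluates a full
source × modality × category × method grid and reports, per modality, the
category with the maximal median MCC — the pre-selection rule that feeds
the signature stage.

## Numerical choices

* The couple-scoring SVM is an in-package dual coordinate-descent solver
  for the L2-regularised hinge loss (deterministic sweep order,
  regularised bias via an augmented constant feature, `tol = 1e-5`,
  ≤ 1000 passes, `C = 1`). A C++ implementation is used because a
  single recovery experiment scores ~10⁵–10⁶ couples; it is validated
  against an independent SVM implementation in the test suite.
* The ridge-logistic fits go through `glmnet` at a single fixed lambda
  (`standardize = FALSE`; inputs are already standardized). Splits so
  small that a class has fewer than two members fall back to an
  in-package Newton/IRLS ridge fit with unpenalized intercept.
* Folds with a single-class training part are skipped and counted, never
  silently scored.
* All randomness flows from named integer seeds through a deterministic
  sub-seed derivation; no stage touches the global RNG state without
  restoring it. Re-running any stage with the same seed is bit-identical
  (the run manifest records wall-clock timings and is the one
  deliberately non-identical artifact).
* Quantiles: type 7 (linear interpolation) everywhere.

## Problem sizes used by the test suite

The suite exercises the pipeline at the sizes its properties are stated
at — planted-signature recovery at `n = 150, p = 50` with 3 planted
features over effect sizes {0.5, 1.0, 1.5, 2.0} × 25 seeds; null
calibration on a zero-effect 145-patient cohort at 10 × 10 repeated CV;
batch-audit power/size at a 2 SD / 0 SD shift × 50 seeds — and uses
reduced feature blocks (8 features per modality-category block) where
the property concerns behaviour, not scale. The `analysis/` drivers run
the full ~1223-features-per-modality configuration.

## Limitations

* Synthetic cohorts are Gaussian with exchangeable block correlation;
  conclusions about patient-level performance cannot be drawn from them.
* The embedding is linear; a batch effect that is purely a covariance
  (not mean) difference could evade both the projection and the mean-
  shift-sensitive clustering.
* Procedure A's consensus aggregation and the SVM-selection threshold
  (mean absolute coefficient) are pragmatic defaults, exposed in
  configuration, not canon.
* Couple scoring is exhaustive; beyond `p_max` features it is the user's
  job to pre-reduce (as the benchmark's category pre-selection does).
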
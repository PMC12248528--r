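# radsig

Network-based radiomic signature extraction and benchmarking for binary
tumor classification.

## The problem

Radiomics converts a segmented tumor volume on MRI into ~1200 quantitative
features per imaging sequence (first-order intensity statistics, 3-D shape,
and GLCM/GLRLM/GLSZM/NGTDM/GLDM texture matrices, computed on the original
image and on Laplacian-of-Gaussian- and wavelet-filtered versions). With
cohorts of ~150 patients, these tables are wide, massively redundant, and
have to be combined with a handful of categorical clinical variables.
Classifying benign vs malignant sinonasal tumors from such data needs
feature selection that is not just accurate but *interpretable*: clinicians
want to see which variables drive the model and how they relate.

`radsig` is an R implementation of that analysis, aimed at people building
or auditing radiomic classification studies. It provides:

- parsing of the pyRadiomics feature-naming dialect
  (`original_*`, `log-sigma-*-mm-3D_*`, `wavelet-*`) into per-column
  category metadata, and z-score / robust (median-IQR) standardization;
- a **synthetic cohort generator** that reproduces the study structure
  (two centers with a batch shift, correlated Original/LoG/Wavelet feature
  blocks, near-duplicate feature pairs, clinical variables calibrated to
  target association strengths), so the whole pipeline is testable without
  patient data;
- clinical association screening with the **bias-corrected Cramér's V**
  `Ṽ = sqrt(max(0, φ² − (k−1)(r−1)/(n−1)) / min(k̃−1, r̃−1))`;
- an unsupervised **batch-effect audit**: robust scaling → 2-D embedding →
  density-based hierarchical clustering (HDBSCAN-style, noise-aware) →
  pairwise Fisher exact cluster enrichment in center and tumor labels;
- **DNetPRO** signature extraction: every feature couple scored by the
  cross-validated MCC of a linear SVM on those two features; top couples
  form a graph; connected components are candidate signatures; each is
  evaluated with ridge logistic regression. Procedure A (selection inside
  an outer CV, consensus signature) and procedure B (rotated stratified
  three-way hold-out) are both implemented;
- an **MCC benchmark harness**: repeated stratified 10-fold CV of every
  pipeline variant (clinical / radiomic / combined × SVM-selection /
  DNetPRO), median ± IQR summaries,
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
  and paired Wilcoxon comparisons between variants.

The repository is an analysis workflow: `analysis/01_simulate.R` …
`06_report.R` are thin narrative drivers over the package functions and
write their tables under `results/`.

## Worked example

```r
library(radsig)

cohort <- generate_cohort(sim_config(seed = 1))
cohort
#> <synthetic_cohort> n = 145 ( 76 malignant / 69 benign ), 2446 radiomic features, 15 clinical variables
#>   centers: A=119, B=26  batch shift: 0.5 SD

head(associate_clinical(cohort$clinical, cohort$labels)[,
     c("variable", "v_corrected", "n_complete")], 4)
#>                    variable v_corrected n_complete
#>  gross_adjacent_involvement   0.3566530        142
#>                    symptoms   0.3544260        145
#>                  tumor_size   0.3489867        144
#>                     pattern   0.1738123        145
```

The three variables planted with population association targets 0.38,
0.41 and 0.38 top the ranking; the rest were planted at 0.10. Extracting
a signature from the CE T1-w LoG block plus encoded clinical covariates:

```r
rad <- subset_by_category(cohort$features, "CE_T1w", "LoG")
enc <- fit_clinical_encoder(cohort$clinical)
X <- cbind_feature_tables(rad, clinical_feature_table(enc, cohort$clinical))$values

res <- procedure_A(X, cohort$labels, dnetpro_config(outer_folds = 5), seed = 1)
summarize_cv(res$cv)
#>   median_mcc         iqr n_scores
#> 1  0.8619048 0.009661172        5

nodes <- export_signature(res$signature, "signature")   # GraphML + CSVs
head(nodes[order(-nodes$degree_centrality), ], 4)
#>                                        feature degree degree_centrality   hub
#>                              clinical.symptoms    392         1.0000000  TRUE
#>                            clinical.tumor_size    392         1.0000000  TRUE
#>  CE_T1w.log-sigma-1-0-mm-3D_glcm_Synthetic0110    365         0.9311224 FALSE
#>            clinical.gross_adjacent_involvement    327         0.8341837 FALSE
```

The outer-test median MCC is 0.86 with IQR 0.01 on this synthetic cohort
(planted effects make it easier than real data), and the clinical
variables `symptoms` and `tumor_size` emerge as the network hubs — the
radiomic nodes attach to them rather than forming hubs of their own. The
number of features in the signature is controlled by
`dnetpro_config(keep_fraction = ...)`, the percentile of retained couples.

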
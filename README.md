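# cariomics

Multi-omic biomarker discovery for early childhood caries: a reusable,
fully tested pipeline from raw SELDI-TOF salivary mass spectra and
checkerboard DNA-DNA hybridization microbial arrays to validated
case/control classifiers and ranked marker panels.

## What it does

Dental caries in children associates both with shifts in the oral
microbiome and with the salivary proteome. Given replicate linear-TOF
spectra per child and an 82-probe checkerboard spot-signal table, the
package:

1. **Preprocesses spectra** with the five-step chain standard for SELDI
   profiles — cube-root variance stabilization, moving-window (≈200
   time-point) baseline subtraction, total-ion-current normalization over
   1,500–16,500 Da, Gaussian smoothing, and peak-based
   dynamic-programming alignment — plus a 2-SD TIC quality-control rule
   and replicate averaging (`preprocess_cohort()`).
2. **Calls peaks** in two stages: positions from the local-max windows of
   the (training) mean profile in 1,500–40,000 Da, then neighbourhood-mean
   intensities per patient (`call_peaks()`).
3. **Normalizes the microbial array** to universal-probe standards:
   `abundance = signal × standard_count / mean(universal)`, removing the
   per-sample DNA amount (`to_abundance()`).
4. **Screens features** with the two-sided Wilcoxon rank-sum test; the
   score is −log₁₀ P (`rank_features()`, `top_k()`).
5. **Validates classifiers** — linear SVM, SVM on the top-k Wilcoxon
   features, random forest — under stratified 70:30 random subsampling,
   40 repeats: mean ± SD test error, sensitivity, specificity, pooled ROC
   and AUC ± SD, and permutation importance (`evaluate()`).
6. **Fuses blocks** by patient matching and column-wise concatenation and
   runs the paired three-condition comparison — microbial-only,
   proteomic-only, combined (`match_and_fuse()`, `run_experiment()`).

A seeded synthetic-cohort generator (`generate_cohort()`,
`generate_null_cohort()`) emulates the target study design — 86
caries-active vs 118 caries-free children, duplicate spectra, ~2,000
planted peaks, two antagonistic differential bacterial communities — and
emits ground truth so every stage is testable without clinical data.

## Worked example

```r
library(cariomics)

cfg <- experiment_config(
  cohort   = cohort_spec(n_case = 30, n_control = 40, n_replicates = 2),
  spectrum = spectrum_model(n_ticks = 8192, n_peaks = 300,
                            n_differential = 30, seed = 2026),
  n_splits = 20, seed = 42)
res <- run_experiment(cfg)
print(res)
```

```
<experiment_result>
 condition        model            error sensitivity specificity   auc
 microbial          svm 19.29% +/- 7.16%       0.783       0.825 0.896
 microbial svm_wilcoxon 14.29% +/- 6.91%       0.806       0.896 0.929
 microbial           rf  7.38% +/- 4.76%       0.900       0.946 0.982
 proteomic          svm  7.14% +/- 5.88%       0.894       0.954 0.985
 proteomic svm_wilcoxon  7.62% +/- 5.66%       0.894       0.946 0.984
 proteomic           rf  7.62% +/- 3.24%       0.872       0.963 0.984
  combined          svm  4.05% +/- 3.55%       0.933       0.979 0.995
  combined svm_wilcoxon  3.81% +/- 3.66%       0.944       0.975 0.996
  combined           rf  2.14% +/- 2.88%       0.961       0.992 0.998
  combined  rf_wilcoxon  3.33% +/- 3.49%       0.967       0.967 0.997
```

Each row is one classifier on one data condition, averaged over the same
20 random 70:30 train/test splits (paired across conditions): mean ± SD
test error, mean sensitivity for detecting caries-active children, mean
specificity, and the pooled-ROC AUC. Fusing the matched microbial and
proteomic blocks lowers the error of every classifier relative to either
block alone on this cohort; `rf_wilcoxon` is the forest refit on only the
top-100 Wilcoxon features of the fused matrix, the check for
dimensionality effects. Marker panels come from the same reports:

```r
head(rf_importance(res$reports$microbial$rf), 5)
#>             feature importance rank
#> Taxon_009 Taxon_009  1.0000000    1
#> Taxon_061 Taxon_061  0.9870892    2
#> Taxon_047 Taxon_047  0.8740932    3
#> Taxon_046 Taxon_046  0.8335095    4
#> Taxon_013 Taxon_013  0.7928456    5
```

Importances are permutation importances averaged over the fitted forests
and scaled to a maximum of one.

See the methods vignette
(`vignettes/caries-multiomics-methods.Rmd`) for the model, its
assumptions, every tunable parameter, and known limitations.

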